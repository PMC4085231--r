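# Solvent placement: a solvent template (a periodic cell of solvent
# residues with edge length `solvlen`, stored in template$props$solvlen) is
# tiled on a grid over the stretched bounding box of the solute; each
# solvent residue is kept or discarded by a per-residue minimum-distance
# filter against the solute, with a van-der-Waals-radius-scaled clash cut.

.mol_bbox <- function(mol) {
  p <- positions(mol)
  if (nrow(p) == 0) return(list(lo = c(0, 0, 0), hi = c(0, 0, 0)))
  list(lo = apply(p, 2, min), hi = apply(p, 2, max))
}

# solvent copies tiled over [lo, hi]; returns per-copy shift vectors
.tile_shifts <- function(lo, hi, solvlen) {
  counts <- pmax(1L, ceiling((hi - lo) / solvlen))
  g <- expand.grid(x = seq_len(counts[1]) - 1L,
                   y = seq_len(counts[2]) - 1L,
                   z = seq_len(counts[3]) - 1L)
  # grid cells start at the stretched-box minimum corner; partial cells at
  # the far faces are included, then pruned by the distance filters
  sweep(as.matrix(g) * solvlen, 2, lo + solvlen / 2, `+`)
}

# template geometry relative to its own center
.template_data <- function(template) {
  tp <- positions(template)
  ctr <- colMeans(tp)
  tp <- sweep(tp, 2, ctr)
  elem <- col_or(template, "atom", "element", "i", 0L)
  res_of <- .residue_of_atoms(template)
  if (any(res_of == 0)) stop("solvent template atoms must belong to residues")
  solvlen <- template$props$solvlen
  if (is.null(solvlen) || solvlen <= 0)
    stop("solvent template must define props$solvlen > 0")
  list(pos = tp, elem = elem, res_of = res_of, solvlen = solvlen)
}

# per-solvent-residue keep decision for one tiled copy
.solvent_filter <- function(spos, selem, res_of, solute_pos, solute_r,
                            closeness, clash_rule) {
  nres <- max(res_of)
  keep <- rep(TRUE, nres)
  dmin <- rep(Inf, nres)
  if (nrow(solute_pos) == 0) return(list(keep = keep, dmin = dmin))
  r2 <- element_vdw(selem)
  d <- outer(rowSums(spos^2), rep(1, nrow(solute_pos))) +
    outer(rep(1, nrow(spos)), rowSums(solute_pos^2)) -
    2 * spos %*% t(solute_pos)
  d[d < 0] <- 0
  d <- sqrt(d)
  cut <- if (clash_rule == "scaled")
    closeness * outer(r2, solute_r, `+`)
  else outer(r2, solute_r, `+`) + closeness
  clash_atom <- apply(d < cut, 1, any)
  dmin_atom <- apply(d, 1, min)
  for (r in seq_len(nres)) {
    rows <- which(res_of == r)
    keep[r] <- !any(clash_atom[rows])
    dmin[r] <- min(dmin_atom[rows])
  }
  list(keep = keep, dmin = dmin)
}

# bulk append of residues + atoms + bonds (O(new) instead of O(total) per
# object, needed when placing thousands of solvent atoms)
.bulk_append <- function(mol, atoms, res_names, res_of_new, bonds) {
  na_new <- length(atoms$elem)
  nr_new <- length(res_names)
  n0a <- n_atoms(mol); n0r <- n_residues(mol); n0b <- n_bonds(mol)
  .ensure_cmp(mol, "atom"); .ensure_cmp(mol, "resd"); .ensure_cmp(mol, "bond")
  grow <- function(type, k) {
    cmp <- mol$cmp[[type]]
    cmp$n <- cmp$n + as.integer(k)
    cmp$cols <- lapply(cmp$cols, function(col) {
      col$data <- c(col$data, if (col$kind == "a") vector("list", k)
                    else if (col$kind == "v") numeric(col$width * k)
                    else rep(.col_default(col$kind), k))
      col
    })
    mol$cmp[[type]] <- cmp
    pre <- paste0(type, ".")
    for (key in names(mol$adj)) {
      if (startsWith(key, pre))
        mol$adj[[key]] <- c(mol$adj[[key]], replicate(k, integer(0), simplify = FALSE))
    }
  }
  grow("atom", na_new); grow("resd", nr_new); grow("bond", nrow(bonds))
  put <- function(type, key, kind, old_all, new_vals, n0, width = 0L) {
    col <- .make_col(mol, type, key, kind, width)
    if (kind == "v") {
      col$data[(n0 * col$width + 1):((n0 + length(new_vals) / col$width) * col$width)] <-
        as.numeric(new_vals)
    } else {
      col$data[(n0 + 1):(n0 + length(new_vals))] <-
        switch(kind, i = as.integer(new_vals), d = as.numeric(new_vals),
               s = as.character(new_vals))
    }
    mol$cmp[[type]]$cols[[.col_key(key)]] <- col
  }
  put("atom", "name", "s", NULL, atoms$name, n0a)
  put("atom", "type", "s", NULL, atoms$type, n0a)
  put("atom", "element", "i", NULL, atoms$elem, n0a)
  put("atom", "pchg", "d", NULL, atoms$pchg, n0a)
  put("atom", "position", "v", NULL, as.vector(t(atoms$pos)), n0a, width = 3L)
  put("resd", "name", "s", NULL, res_names, n0r)
  put("resd", "seq", "i", NULL, n0r + seq_len(nr_new), n0r)
  put("resd", "solvent", "i", NULL, rep(1L, nr_new), n0r)
  if (nrow(bonds)) put("bond", "order", "i", NULL, bonds[, 3], n0b)
  # adjacency rows
  k_ra <- .ensure_adj(mol, "resd", "atom"); k_ar <- .ensure_adj(mol, "atom", "resd")
  for (k in seq_len(na_new)) {
    aid <- n0a + k; rid <- n0r + res_of_new[k]
    mol$adj[[k_ra]][[rid]] <- c(mol$adj[[k_ra]][[rid]], aid)
    mol$adj[[k_ar]][[aid]] <- rid
  }
  if (nrow(bonds)) {
    k_ba <- .ensure_adj(mol, "bond", "atom"); k_ab <- .ensure_adj(mol, "atom", "bond")
    k_aa <- .ensure_adj(mol, "atom", "atom")
    for (b in seq_len(nrow(bonds))) {
      bid <- n0b + b; i <- n0a + bonds[b, 1]; j <- n0a + bonds[b, 2]
      mol$adj[[k_ba]][[bid]] <- c(i, j)
      mol$adj[[k_ab]][[i]] <- c(mol$adj[[k_ab]][[i]], bid)
      mol$adj[[k_ab]][[j]] <- c(mol$adj[[k_ab]][[j]], bid)
      mol$adj[[k_aa]][[i]] <- c(mol$adj[[k_aa]][[i]], j)
      mol$adj[[k_aa]][[j]] <- c(mol$adj[[k_aa]][[j]], i)
    }
  }
  invisible(mol)
}

.solvate_impl <- function(mol, template, region_lo, region_hi, closeness,
                          clash_rule, keep_fun) {
  td <- .template_data(template)
  solute_pos <- positions(mol)
  solute_r <- element_vdw(col_or(mol, "atom", "element", "i", 0L))
  shifts <- .tile_shifts(region_lo, region_hi, td$solvlen)
  tnames <- col_or(template, "atom", "name", "s", "")
  ttypes <- col_or(template, "atom", "type", "s", "")
  tpchg <- col_or(template, "atom", "pchg", "d", 0)
  trnames <- col_or(template, "resd", "name", "s", "WAT")
  trnames[!nzchar(trnames)] <- "WAT"
  tbt <- bond_table(template)
  nres_t <- max(td$res_of)
  acc_pos <- list(); acc_resof <- list(); acc_aidx <- list()
  acc_rname <- character(0)
  nres_added <- 0L
  for (s in seq_len(nrow(shifts))) {
    shift <- shifts[s, ]
    spos <- sweep(td$pos, 2, shift, `+`)
    flt <- .solvent_filter(spos, td$elem, td$res_of, solute_pos, solute_r,
                           closeness, clash_rule)
    cent <- t(vapply(seq_len(nres_t), function(r)
      colMeans(spos[td$res_of == r, , drop = FALSE]), numeric(3)))
    for (r in which(flt$keep)) {
      if (!keep_fun(cent[r, ], flt$dmin[r])) next
      rows <- which(td$res_of == r)
      nres_added <- nres_added + 1L
      acc_pos[[nres_added]] <- spos[rows, , drop = FALSE]
      acc_aidx[[nres_added]] <- rows
      acc_resof[[nres_added]] <- rep(nres_added, length(rows))
      acc_rname[nres_added] <- trnames[r]
    }
  }
  if (nres_added > 0L) {
    tmpl_rows <- unlist(acc_aidx)
    new_of_row <- integer(0)    # template atom row (per placed residue) -> new rel id
    atoms <- list(name = tnames[tmpl_rows], type = ttypes[tmpl_rows],
                  elem = td$elem[tmpl_rows], pchg = tpchg[tmpl_rows],
                  pos = do.call(rbind, acc_pos))
    res_of_new <- unlist(acc_resof)
    # intra-residue bonds, remapped per placed residue
    bonds <- matrix(0L, 0, 3)
    if (nrow(tbt)) {
      off <- 0L
      blist <- vector("list", nres_added)
      for (k in seq_len(nres_added)) {
        rows <- acc_aidx[[k]]
        sel <- which(tbt[, 1] %in% rows & tbt[, 2] %in% rows)
        if (length(sel)) {
          bi <- match(tbt[sel, 1], rows) + off
          bj <- match(tbt[sel, 2], rows) + off
          blist[[k]] <- cbind(bi, bj, pmax(1L, tbt[sel, 3]))
        }
        off <- off + length(rows)
      }
      bonds <- do.call(rbind, c(list(matrix(0L, 0, 3)), blist[!vapply(blist, is.null, logical(1))]))
    }
    .bulk_append(mol, atoms, acc_rname, res_of_new, bonds)
  }
  nres_added
}

#' Build solvation environments
#'
#' `solvate_shell()` surrounds the whole solute with a shell of solvent:
#' the solute bounding box is stretched by `extent` on all sides, solvent
#' template copies are tiled with spacing `solvlen`, and each solvent
#' residue is kept iff (a) no solvent atom comes closer to a solute atom
#' than the clash cut and (b) its minimum solute distance is at most
#' `extent`. The clash cut is `closeness * (r1 + r2)` over the involved
#' van der Waals radii (`clash_rule = "scaled"`, the default), or
#' `r1 + r2 + closeness` with `clash_rule = "additive"`.
#'
#' `solvate_box()` fills the cuboid bounding box stretched by `buffer`,
#' `solvate_oct()` additionally clips the corners to the truncated
#' octahedron (`|x| + |y| + |z| <= 3a/4` on the cube of side `a`, so it
#' never places more solvents than the box at equal buffer), and
#' `solvate_cap()` keeps solvent residues whose centroid lies within
#' `radius` of `center`. Box metadata is recorded in `mol$props$box` for
#' the topology writer. Placement is deterministic.
#'
#' @param mol the solute molecule, modified in place.
#' @param template solvent template molecule (residues + positions +
#'   `props$solvlen`).
#' @param closeness clash scale (dimensionless for `"scaled"`, Angstrom
#'   for `"additive"`); must be positive.
#' @param extent shell border distance in Angstrom (shell mode; must
#'   exceed the closeness cut).
#' @param clash_rule `"scaled"` or `"additive"`.
#' @return number of solvent residues added, invisibly.
#' @export
solvate_shell <- function(mol, template, closeness, extent,
                          clash_rule = c("scaled", "additive")) {
  clash_rule <- match.arg(clash_rule)
  if (!is.numeric(closeness) || closeness <= 0) stop("closeness must be positive")
  if (!is.numeric(extent) || extent <= 0) stop("extent must be positive")
  if (extent <= closeness && clash_rule == "additive")
    stop("extent must exceed closeness")
  bb <- .mol_bbox(mol)
  added <- .solvate_impl(mol, template, bb$lo - extent, bb$hi + extent,
                         closeness, clash_rule,
                         keep_fun = function(cent, dmin) dmin <= extent)
  invisible(added)
}

#' @rdname solvate_shell
#' @param buffer box buffer in Angstrom added to each side of the solute
#'   bounding box.
#' @export
solvate_box <- function(mol, template, buffer, closeness = 1.0,
                        clash_rule = c("scaled", "additive")) {
  clash_rule <- match.arg(clash_rule)
  if (!is.numeric(buffer) || buffer <= 0) stop("buffer must be positive")
  if (closeness <= 0) stop("closeness must be positive")
  bb <- .mol_bbox(mol)
  lo <- bb$lo - buffer; hi <- bb$hi + buffer
  added <- .solvate_impl(mol, template, lo, hi, closeness, clash_rule,
                         keep_fun = function(cent, dmin)
                           all(cent >= lo) && all(cent <= hi))
  mol$props$box <- list(dims = hi - lo, center = (hi + lo) / 2, shape = "box")
  invisible(added)
}

#' @rdname solvate_shell
#' @export
solvate_oct <- function(mol, template, buffer, closeness = 1.0,
                        clash_rule = c("scaled", "additive")) {
  clash_rule <- match.arg(clash_rule)
  if (!is.numeric(buffer) || buffer <= 0) stop("buffer must be positive")
  bb <- .mol_bbox(mol)
  lo <- bb$lo - buffer; hi <- bb$hi + buffer
  ctr <- (hi + lo) / 2
  a <- max(hi - lo)
  added <- .solvate_impl(mol, template, lo, hi, closeness, clash_rule,
                         keep_fun = function(cent, dmin) {
                           u <- abs(cent - ctr)
                           all(cent >= lo) && all(cent <= hi) &&
                             sum(u) <= 3 * a / 4
                         })
  mol$props$box <- list(dims = hi - lo, center = ctr, shape = "oct", a = a)
  invisible(added)
}

#' @rdname solvate_shell
#' @param center cap center (length-3, Angstrom).
#' @param radius cap radius (Angstrom, positive).
#' @export
solvate_cap <- function(mol, template, center, radius, closeness = 1.0,
                        clash_rule = c("scaled", "additive")) {
  clash_rule <- match.arg(clash_rule)
  if (!is.numeric(radius) || radius <= 0) stop("cap radius must be positive")
  center <- as.numeric(center)
  added <- .solvate_impl(mol, template, center - radius, center + radius,
                         closeness, clash_rule,
                         keep_fun = function(cent, dmin)
                           sqrt(sum((cent - center)^2)) <= radius)
  mol$props$cap <- list(center = center, radius = radius)
  invisible(added)
}

#' Add counter-ions
#'
#' In `"auto"` mode, places `ceiling(|net charge|)` ions of the template's
#' sign (expected to oppose the solute net charge computed from the `pchg`
#' atom property); with a numeric `count`, places exactly that many. Each
#' ion goes to the grid point minimizing its electrostatic energy against
#' all atoms placed so far, at least `min_dist` from every existing atom.
#'
#' @param mol the molecule, modified in place.
#' @param ion_template single-atom molecule carrying `name`, `element`,
#'   `type` and `pchg`.
#' @param count `"auto"` or a non-negative integer.
#' @param min_dist minimum distance to existing atoms (Angstrom).
#' @param grid_spacing potential-grid spacing (Angstrom).
#' @return number of ions placed, invisibly.
#' @export
addions <- function(mol, ion_template, count = "auto", min_dist = 3.0,
                    grid_spacing = 1.0) {
  stopifnot(is_molecule(ion_template), n_atoms(ion_template) == 1L)
  qi <- get_d(handle(ion_template, "atom", 1), "pchg")
  if (identical(count, "auto")) {
    q <- col_or(mol, "atom", "pchg", "d", NA_real_)
    if (anyNA(q)) stop("addions auto mode needs partial charges on all atoms")
    net <- sum(q)
    if (abs(net) < 1e-6) {
      message("net charge is zero; no ions added")
      return(invisible(0L))
    }
    count <- ceiling(abs(net) / max(abs(qi), 1e-9))
  }
  count <- as.integer(count)
  if (count < 0) stop("ion count must be non-negative")
  placed <- 0L
  for (k in seq_len(count)) {
    pos <- positions(mol)
    q <- col_or(mol, "atom", "pchg", "d", 0)
    bb <- .mol_bbox(mol)
    lo <- bb$lo - 5; hi <- bb$hi + 5
    gr <- expand.grid(x = seq(lo[1], hi[1], by = grid_spacing),
                      y = seq(lo[2], hi[2], by = grid_spacing),
                      z = seq(lo[3], hi[3], by = grid_spacing))
    gr <- as.matrix(gr)
    if (nrow(pos) > 0) {
      d <- outer(rowSums(gr^2), rep(1, nrow(pos))) +
        outer(rep(1, nrow(gr)), rowSums(pos^2)) - 2 * gr %*% t(pos)
      d[d < 0] <- 0
      d <- sqrt(d)
      ok <- apply(d >= min_dist, 1, all)
      if (!any(ok)) stop("no grid point at least ", min_dist, " A from all atoms")
      pot <- (1 / pmax(d, 0.1)) %*% q
      en <- qi * pot
      en[!ok] <- Inf
      best <- which.min(en)
    } else best <- 1L
    target <- gr[best, ]
    r <- create_object(mol, "resd")
    ta <- handle(ion_template, "atom", 1)
    set_s(r, "name", get_s(ta, "name"))
    set_i(r, "seq", r$id)
    a <- create_object(mol, "atom")
    set_s(a, "name", get_s(ta, "name"))
    set_i(a, "element", get_i(ta, "element"))
    tv <- try_prop(ta, "type", "s")
    set_s(a, "type", if (tv$found) tv$value else get_s(ta, "name"))
    set_d(a, "pchg", qi)
    set_v(a, "position", target)
    relate(r, a)
    placed <- placed + 1L
  }
  invisible(placed)
}

#' Synthetic solvent cube template
#'
#' A 216-water cube built on a regular 6 x 6 x 6 grid (3.1 Angstrom
#' spacing, TIP3P-like geometry, charges -0.834/+0.417 e, types OW/HW),
#' centered at the origin with `props$solvlen = 18.6`. This is an
#' idealized synthetic lattice, not an equilibrated liquid snapshot.
#'
#' @param nside waters per edge (default 6).
#' @param spacing lattice spacing in Angstrom (default 3.1).
#' @return a molecule usable as a solvent template.
#' @export
water_box_template <- function(nside = 6L, spacing = 3.1) {
  mol <- new_molecule("WATBOX")
  # three fixed orientations cycled deterministically
  ors <- list(diag(3),
              matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3, 3),
              matrix(c(1, 0, 0, 0, 0, 1, 0, -1, 0), 3, 3))
  geo <- rbind(O = c(0, 0, 0),
               H1 = c(0.9572, 0, 0),
               H2 = c(-0.2399872, 0.9266272, 0))
  k <- 0L
  for (ix in seq_len(nside)) for (iy in seq_len(nside)) for (iz in seq_len(nside)) {
    k <- k + 1L
    ctr <- (c(ix, iy, iz) - (nside + 1) / 2) * spacing
    R <- ors[[(k %% 3L) + 1L]]
    r <- create_object(mol, "resd")
    set_s(r, "name", "WAT"); set_i(r, "seq", k)
    ids <- integer(3)
    info <- list(c("O", "OW", 8L, -0.834), c("H1", "HW", 1L, 0.417),
                 c("H2", "HW", 1L, 0.417))
    for (j in 1:3) {
      a <- create_object(mol, "atom")
      set_s(a, "name", info[[j]][[1]])
      set_s(a, "type", info[[j]][[2]])
      set_i(a, "element", as.integer(info[[j]][[3]]))
      set_d(a, "pchg", as.numeric(info[[j]][[4]]))
      set_v(a, "position", ctr + as.numeric(geo[j, ] %*% R))
      relate(r, a)
      ids[j] <- a$id
    }
    add_bond(mol, ids[1], ids[2], 1L)
    add_bond(mol, ids[1], ids[3], 1L)
  }
  mol$props$solvlen <- nside * spacing
  mol
}
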