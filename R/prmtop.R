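# AMBER prmtop writer (modern %FLAG dialect) and ASCII coordinate writer.

.fmt_section <- function(flag, fmt, values) {
  out <- c(sprintf("%%FLAG %s", flag), sprintf("%%FORMAT(%s)", fmt))
  if (length(values) == 0) return(c(out, ""))
  if (fmt == "10I8") {
    per <- 10L; body <- sprintf("%8d", as.integer(values))
  } else if (fmt == "5E16.8") {
    per <- 5L; body <- sprintf("%16.8E", as.numeric(values))
  } else if (fmt == "20a4") {
    per <- 20L; body <- sprintf("%-4s", substr(as.character(values), 1, 4))
  } else if (fmt == "1a80") {
    per <- 1L; body <- sprintf("%-80s", as.character(values))
  } else stop("unknown prmtop format ", fmt)
  idx <- split(seq_along(body), (seq_along(body) - 1L) %/% per)
  c(out, vapply(idx, function(ii) paste(body[ii], collapse = ""), character(1)))
}

# residue partition as contiguous ranges; atoms outside any residue are
# collected into a trailing default residue
.residue_pointers <- function(mol) {
  n <- n_atoms(mol)
  res_of <- .residue_of_atoms(mol)
  if (n == 0) stop("cannot write topology for a molecule with zero atoms")
  if (all(res_of == 0)) {
    return(list(labels = "MOL", first = 1L))
  }
  if (any(res_of == 0))
    stop("atoms ", paste(which(res_of == 0), collapse = ", "),
         " belong to no residue")
  rname <- col_or(mol, "resd", "name", "s", "RES")
  ord <- order(res_of, seq_len(n))
  if (!identical(ord, seq_len(n)))
    stop("residues must partition atoms contiguously for the topology writer")
  first <- match(sort(unique(res_of)), res_of)
  labels <- rname[sort(unique(res_of))]
  labels[!nzchar(labels)] <- "RES"
  list(labels = labels, first = first)
}

#' Write an AMBER topology (prmtop) file
#'
#' Emits the modern `%VERSION` / `%FLAG` prmtop layout: POINTERS,
#' ATOM_NAME, CHARGE (partial charges times 18.2223, so that q_i q_j / r
#' over prmtop charges is kcal/mol), ATOMIC_NUMBER, MASS,
#' ATOM_TYPE_INDEX, NUMBER_EXCLUDED_ATOMS, NONBONDED_PARM_INDEX,
#' RESIDUE_LABEL/POINTER, bond/angle/dihedral force-constant and term
#' index sections split into with-hydrogen and without-hydrogen groups
#' (keyed on element), SCEE/SCNB scale factors, LENNARD_JONES
#' A/B coefficients, EXCLUDED_ATOMS_LIST, AMBER_ATOM_TYPE, RADII and
#' SCREEN, plus box sections when box metadata is present. Term index
#' encoding follows the AMBER convention: coordinate-array offsets
#' (3*(id-1)), negative third index to suppress duplicate 1-4 pairs, and
#' negative third+fourth for impropers.
#'
#' @param mol molecule with named, typed, charged atoms, positions,
#'   enumerated terms and residues.
#' @param ff force field resolving every term parameter.
#' @param file output path or connection; "" returns lines only.
#' @return invisibly, the lines written.
#' @export
write_amber_prmtop <- function(mol, ff, file = "") {
  n <- n_atoms(mol)
  if (n == 0) stop("cannot write topology for a molecule with zero atoms")
  nm <- col_or(mol, "atom", "name", "s", "")
  ty <- col_of(mol, "atom", "type", "s")
  if (any(!nzchar(ty)))
    stop("atoms ", paste(which(!nzchar(ty)), collapse = ", "), " have no type")
  q <- col_or(mol, "atom", "pchg", "d", 0)
  elem <- col_or(mol, "atom", "element", "i", 0L)
  mass <- vapply(ty, function(t) ff_mass(ff, t), numeric(1))
  utypes <- unique(ty)
  tindex <- match(ty, utypes)
  ntypes <- length(utypes)
  isH <- elem == 1L

  # bonds
  bt <- bond_table(mol)
  bkeys <- character(0); bparams <- list()
  bond_rows <- matrix(0L, nrow(bt), 3)
  for (b in seq_len(nrow(bt))) {
    p <- ff_bond(ff, ty[bt[b, 1]], ty[bt[b, 2]])
    key <- paste(p, collapse = "|")
    k <- match(key, bkeys)
    if (is.na(k)) { bkeys <- c(bkeys, key); bparams <- c(bparams, list(p)); k <- length(bkeys) }
    bond_rows[b, ] <- c(bt[b, 1], bt[b, 2], k)
  }
  bH <- which(isH[bond_rows[, 1]] | isH[bond_rows[, 2]])
  bA <- setdiff(seq_len(nrow(bt)), bH)

  # angles
  ta <- .term_atoms(mol, "angl", 3L)
  akeys <- character(0); aparams <- list()
  ang_rows <- matrix(0L, nrow(ta), 4)
  for (t in seq_len(nrow(ta))) {
    p <- ff_angle(ff, ty[ta[t, 1]], ty[ta[t, 2]], ty[ta[t, 3]])
    key <- paste(p, collapse = "|")
    k <- match(key, akeys)
    if (is.na(k)) { akeys <- c(akeys, key); aparams <- c(aparams, list(p)); k <- length(akeys) }
    ang_rows[t, ] <- c(ta[t, ], k)
  }
  aH <- which(rowSums(matrix(isH[ang_rows[, 1:3]], ncol = 3)) > 0)
  aA <- setdiff(seq_len(nrow(ta)), aH)

  # dihedrals (proper + improper), one entry per Fourier term
  cls <- .pair_classes(mol)
  dkeys <- character(0); dparams <- list()
  dpar <- function(term) {
    key <- paste(term$pk / term$idivf, term$phase, term$pn, sep = "|")
    k <- match(key, dkeys)
    if (is.na(k)) {
      dkeys <<- c(dkeys, key)
      dparams <<- c(dparams, list(list(pk = term$pk / term$idivf,
                                       phase = term$phase, pn = term$pn)))
      k <- length(dkeys)
    }
    k
  }
  drows <- list()
  seen14 <- new.env(parent = emptyenv())
  tt <- .term_atoms(mol, "tors", 4L)
  for (t in seq_len(nrow(tt))) {
    at <- tt[t, ]
    terms <- ff_torsion(ff, ty[at[1]], ty[at[2]], ty[at[3]], ty[at[4]])
    key14 <- cls$key(at[1], at[4])
    count14 <- !is.null(cls$p14[[key14]]) && is.null(seen14[[key14]])
    if (count14) assign(key14, TRUE, seen14)
    for (m in seq_along(terms)) {
      neg3 <- !(count14 && m == 1L)
      aa <- at
      if (neg3 && aa[3] == 1L) aa <- rev(aa)
      drows[[length(drows) + 1L]] <-
        list(a = aa, pidx = dpar(terms[[m]]), neg3 = neg3, neg4 = FALSE,
             hasH = any(isH[at]))
    }
  }
  to <- .term_atoms(mol, "oops", 4L)
  for (t in seq_len(nrow(to))) {
    at <- to[t, ]
    p <- ff_improper(ff, ty[at[1]], ty[at[2]], ty[at[3]], ty[at[4]])
    if (is.null(p)) next
    drows[[length(drows) + 1L]] <-
      list(a = at, pidx = dpar(p), neg3 = TRUE, neg4 = TRUE, hasH = any(isH[at]))
  }
  dH <- which(vapply(drows, `[[`, logical(1), "hasH"))
  dA <- setdiff(seq_along(drows), dH)

  # exclusions (1-2, 1-3, 1-4), ascending per atom; empty list -> single 0
  excl <- replicate(n, integer(0), simplify = FALSE)
  for (env in list(cls$p12, cls$p13, cls$p14)) {
    for (key in ls(env)) {
      ij <- as.integer(strsplit(key, " ", fixed = TRUE)[[1]])
      excl[[ij[1]]] <- c(excl[[ij[1]]], ij[2])
    }
  }
  excl <- lapply(excl, function(x) sort(unique(x)))
  nexc <- vapply(excl, function(x) max(1L, length(x)), integer(1))
  excl_list <- unlist(lapply(excl, function(x) if (length(x)) x else 0L))

  # Lennard-Jones tables
  npairs <- ntypes * (ntypes + 1L) / 2L
  acoef <- numeric(npairs); bcoef <- numeric(npairs)
  vdwp <- lapply(utypes, function(t) ff_vdw(ff, t))
  for (i in seq_len(ntypes)) for (j in seq_len(i)) {
    idx <- i * (i - 1L) / 2L + j
    rm <- vdwp[[i]][["rmin2"]] + vdwp[[j]][["rmin2"]]
    ep <- sqrt(vdwp[[i]][["eps"]] * vdwp[[j]][["eps"]])
    acoef[idx] <- ep * rm^12
    bcoef[idx] <- 2 * ep * rm^6
  }
  ico <- integer(ntypes * ntypes)
  for (i in seq_len(ntypes)) for (j in seq_len(ntypes)) {
    lo <- min(i, j); hi <- max(i, j)
    ico[ntypes * (i - 1L) + j] <- hi * (hi - 1L) / 2L + lo
  }

  res <- .residue_pointers(mol)
  nres <- length(res$labels)
  hasbox <- !is.null(mol$props$box)

  dih_arr <- function(idx) {
    unlist(lapply(drows[idx], function(d) {
      v <- 3L * (d$a - 1L)
      if (d$neg3) v[3] <- -v[3]
      if (d$neg4) v[4] <- -v[4]
      c(v, d$pidx)
    }))
  }
  radii <- col_or(mol, "atom", "born", "d", NA_real_)
  radii[is.na(radii)] <- element_born(elem[is.na(radii)])

  pointers <- c(n, ntypes, length(bH), length(bA), length(aH), length(aA),
                length(dH), length(dA), 0L, 0L, sum(nexc), nres,
                length(bA), length(aA), length(dA), length(bkeys),
                length(akeys), length(dkeys), ntypes, 0L, 0L, 0L, 0L, 0L,
                0L, 0L, 0L, if (hasbox) 1L else 0L,
                max(diff(c(res$first, n + 1L))), 0L, 0L)

  lines <- c(sprintf("%%VERSION  VERSION_STAMP = V0001.000  DATE = 01/01/00  00:00:00"),
             .fmt_section("TITLE", "20a4", if (nzchar(mol$name)) mol$name else "MOL"),
             .fmt_section("POINTERS", "10I8", pointers),
             .fmt_section("ATOM_NAME", "20a4",
                          ifelse(nzchar(nm), nm, element_symbol(elem))),
             .fmt_section("CHARGE", "5E16.8", q * AMBER_CHARGE_SCALE),
             .fmt_section("ATOMIC_NUMBER", "10I8", elem),
             .fmt_section("MASS", "5E16.8", mass),
             .fmt_section("ATOM_TYPE_INDEX", "10I8", tindex),
             .fmt_section("NUMBER_EXCLUDED_ATOMS", "10I8", nexc),
             .fmt_section("NONBONDED_PARM_INDEX", "10I8", ico),
             .fmt_section("RESIDUE_LABEL", "20a4", res$labels),
             .fmt_section("RESIDUE_POINTER", "10I8", res$first),
             .fmt_section("BOND_FORCE_CONSTANT", "5E16.8",
                          vapply(bparams, function(p) p[["k"]], numeric(1))),
             .fmt_section("BOND_EQUIL_VALUE", "5E16.8",
                          vapply(bparams, function(p) p[["r0"]], numeric(1))),
             .fmt_section("ANGLE_FORCE_CONSTANT", "5E16.8",
                          vapply(aparams, function(p) p[["k"]], numeric(1))),
             .fmt_section("ANGLE_EQUIL_VALUE", "5E16.8",
                          vapply(aparams, function(p) p[["theta0"]] * pi / 180, numeric(1))),
             .fmt_section("DIHEDRAL_FORCE_CONSTANT", "5E16.8",
                          vapply(dparams, function(p) p$pk, numeric(1))),
             .fmt_section("DIHEDRAL_PERIODICITY", "5E16.8",
                          vapply(dparams, function(p) p$pn, numeric(1))),
             .fmt_section("DIHEDRAL_PHASE", "5E16.8",
                          vapply(dparams, function(p) p$phase * pi / 180, numeric(1))),
             .fmt_section("SCEE_SCALE_FACTOR", "5E16.8", rep(1.2, length(dparams))),
             .fmt_section("SCNB_SCALE_FACTOR", "5E16.8", rep(2.0, length(dparams))),
             .fmt_section("SOLTY", "5E16.8", rep(0, ntypes)),
             .fmt_section("LENNARD_JONES_ACOEF", "5E16.8", acoef),
             .fmt_section("LENNARD_JONES_BCOEF", "5E16.8", bcoef),
             .fmt_section("BONDS_INC_HYDROGEN", "10I8",
                          unlist(lapply(bH, function(b)
                            c(3L * (bond_rows[b, 1:2] - 1L), bond_rows[b, 3])))),
             .fmt_section("BONDS_WITHOUT_HYDROGEN", "10I8",
                          unlist(lapply(bA, function(b)
                            c(3L * (bond_rows[b, 1:2] - 1L), bond_rows[b, 3])))),
             .fmt_section("ANGLES_INC_HYDROGEN", "10I8",
                          unlist(lapply(aH, function(t)
                            c(3L * (ang_rows[t, 1:3] - 1L), ang_rows[t, 4])))),
             .fmt_section("ANGLES_WITHOUT_HYDROGEN", "10I8",
                          unlist(lapply(aA, function(t)
                            c(3L * (ang_rows[t, 1:3] - 1L), ang_rows[t, 4])))),
             .fmt_section("DIHEDRALS_INC_HYDROGEN", "10I8", dih_arr(dH)),
             .fmt_section("DIHEDRALS_WITHOUT_HYDROGEN", "10I8", dih_arr(dA)),
             .fmt_section("EXCLUDED_ATOMS_LIST", "10I8", excl_list),
             .fmt_section("HBOND_ACOEF", "5E16.8", numeric(0)),
             .fmt_section("HBOND_BCOEF", "5E16.8", numeric(0)),
             .fmt_section("HBCUT", "5E16.8", numeric(0)),
             .fmt_section("AMBER_ATOM_TYPE", "20a4", ty),
             .fmt_section("TREE_CHAIN_CLASSIFICATION", "20a4", rep("BLA", n)),
             .fmt_section("JOIN_ARRAY", "10I8", rep(0L, n)),
             .fmt_section("IROTAT", "10I8", rep(0L, n)),
             .fmt_section("RADII", "5E16.8", radii),
             .fmt_section("SCREEN", "5E16.8", element_screen(elem)),
             .fmt_section("IPOL", "10I8", 0L))
  if (hasbox) {
    comp <- .connected_components(mol)
    box <- mol$props$box$dims
    nspm <- length(comp)
    res_of <- .residue_of_atoms(mol)
    rsolv <- col_or(mol, "resd", "solvent", "i", 0L)
    first_solvent <- match(1L, vapply(comp, function(ids)
      as.integer(any(rsolv[res_of[ids][res_of[ids] > 0]] == 1L)), integer(1)))
    lines <- c(lines,
               .fmt_section("SOLVENT_POINTERS", "10I8",
                            c(nres, nspm, if (is.na(first_solvent)) nspm + 1L else first_solvent)),
               .fmt_section("ATOMS_PER_MOLECULE", "10I8", lengths(comp)),
               .fmt_section("BOX_DIMENSIONS", "5E16.8", c(90, box)))
  }
  if (!identical(file, "")) writeLines(lines, file)
  invisible(lines)
}

.connected_components <- function(mol) {
  n <- n_atoms(mol)
  nbr <- neighbors(mol)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] > 0L) next
    cur <- cur + 1L
    stack <- s
    while (length(stack)) {
      v <- stack[[length(stack)]]; stack <- stack[-length(stack)]
      if (comp[v] > 0L) next
      comp[v] <- cur
      stack <- c(stack, nbr[[v]][comp[nbr[[v]]] == 0L])
    }
  }
  split(seq_len(n), comp)
}

#' Write AMBER ASCII coordinates (inpcrd/restart layout)
#'
#' Title line, atom count, coordinates six per line in `%12.7f`, and a
#' trailing box line (edges + 90-degree angles) when box metadata exists.
#'
#' @inheritParams write_pdb
#' @export
write_inpcrd <- function(mol, file = "") {
  n <- n_atoms(mol)
  if (n == 0 || is.null(.get_col(mol, "atom", "position")))
    stop("cannot write coordinates: no atom positions")
  pos <- positions(mol)
  flat <- as.vector(t(pos))
  idx <- split(seq_along(flat), (seq_along(flat) - 1L) %/% 6L)
  lines <- c(if (nzchar(mol$name)) mol$name else "MOL",
             sprintf("%5d", n),
             vapply(idx, function(ii) paste(sprintf("%12.7f", flat[ii]), collapse = ""),
                    character(1)))
  if (!is.null(mol$props$box))
    lines <- c(lines, paste(sprintf("%12.7f", c(mol$props$box$dims, 90, 90, 90)),
                            collapse = ""))
  if (!identical(file, "")) writeLines(lines, file)
  invisible(lines)
}
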