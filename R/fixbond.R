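# Bond-order perception and hydrogen addition.

.valence_cap <- function(elem, fchg = 0L) {
  base <- c(`1` = 1L, `5` = 4L, `6` = 4L, `7` = 4L, `8` = 3L, `9` = 1L,
            `14` = 4L, `15` = 5L, `16` = 6L, `17` = 1L, `35` = 1L, `53` = 1L)
  v <- base[as.character(elem)]
  v[is.na(v)] <- 6L
  as.integer(v)
}

# standard (neutral) valence, charge-adjusted for implicit-H accounting
.valence_std <- function(elem, fchg = 0L) {
  v <- element_valence(elem)
  adj <- ifelse(elem == 5L, v - fchg, v + fchg)  # boron: [BH4-] has 4 bonds
  pmax(0L, as.integer(adj))
}

#' Perceive bond orders
#'
#' Assigns an integer order to every bond whose order is unset (0) or
#' delocalized (4, MOL2 aromatic), applying three rules in sequence:
#'
#' 1. *hard rule* - fixed-order functional-group templates (carboxylate,
#'    nitro, guanidinium, phosphate, sulfone);
#' 2. *length rule* - order bands from element-pair covalent-radius sums
#'    with 0.05 Angstrom slack between bands; bond lengths between bands
#'    mark the bond as conjugated;
#' 3. *conjugation rule* - alternating single/double assignment over the
#'    remaining conjugated systems (Kekulization), ties broken
#'    lowest-atom-index-first.
#'
#' The final assignment never exceeds any atom's maximum valence; an
#' unassignable system raises an error listing the offending atoms.
#'
#' @param mol a molecule whose atoms have `element` (and `position` when
#'   the length rule is needed).
#' @return the molecule, invisibly.
#' @export
fixbond <- function(mol) {
  nb <- n_bonds(mol)
  if (nb == 0L) return(invisible(mol))
  bt <- bond_table(mol)
  ord <- bt[, 3]
  elem <- col_or(mol, "atom", "element", "i", 0L)
  fchg <- col_or(mol, "atom", "fchg", "i", 0L)
  nbr <- neighbors(mol)
  deg <- lengths(nbr)
  bond_of <- function(i, j) which((bt[, 1] == i & bt[, 2] == j) | (bt[, 1] == j & bt[, 2] == i))[1]

  # --- hard rule: functional-group templates ------------------------------
  unset <- function(b) ord[b] == 0L
  for (c_at in which(elem == 6L)) {
    os <- Filter(function(j) elem[j] == 8L && deg[j] == 1L && unset(bond_of(c_at, j)),
                 nbr[[c_at]])
    if (length(os) == 2L) {   # carboxylate / carboxyl
      os <- sort(unlist(os))
      ord[bond_of(c_at, os[1])] <- 2L
      ord[bond_of(c_at, os[2])] <- 1L
    }
    ns <- Filter(function(j) elem[j] == 7L, nbr[[c_at]])
    if (length(ns) == 3L && deg[c_at] == 3L) {  # guanidinium
      ns <- sort(unlist(ns))
      bs <- vapply(ns, function(j) bond_of(c_at, j), integer(1))
      if (all(ord[bs] == 0L)) {
        ord[bs[1]] <- 2L; ord[bs[-1]] <- 1L
      }
    }
  }
  for (n_at in which(elem == 7L)) {   # nitro
    os <- Filter(function(j) elem[j] == 8L && deg[j] == 1L && unset(bond_of(n_at, j)),
                 nbr[[n_at]])
    if (length(os) == 2L) {
      os <- sort(unlist(os))
      ord[bond_of(n_at, os[1])] <- 2L
      ord[bond_of(n_at, os[2])] <- 1L
    }
  }
  for (p_at in which(elem == 15L)) {  # phosphate: one P=O
    os <- sort(unlist(Filter(function(j) elem[j] == 8L && deg[j] == 1L &&
                               unset(bond_of(p_at, j)), nbr[[p_at]])))
    if (length(os) >= 1L) {
      ord[bond_of(p_at, os[1])] <- 2L
      for (j in os[-1]) ord[bond_of(p_at, j)] <- 1L
    }
  }
  for (s_at in which(elem == 16L)) {  # sulfone/sulfate: two S=O
    os <- sort(unlist(Filter(function(j) elem[j] == 8L && deg[j] == 1L &&
                               unset(bond_of(s_at, j)), nbr[[s_at]])))
    if (deg[s_at] >= 3L && length(os) >= 2L) {
      ord[bond_of(s_at, os[1])] <- 2L
      ord[bond_of(s_at, os[2])] <- 2L
      for (j in os[-(1:2)]) ord[bond_of(s_at, j)] <- 1L
    }
  }

  # --- length rule --------------------------------------------------------
  cand <- which(ord == 4L)            # delocalized bonds go to kekulization
  todo <- which(ord == 0L)
  if (length(todo)) {
    if (is.null(.get_col(mol, "atom", "position")))
      stop("fixbond length rule needs atom positions for ", length(todo), " bonds")
    pos <- positions(mol)
    for (b in todo) {
      i <- bt[b, 1]; j <- bt[b, 2]
      d <- sqrt(sum((pos[i, ] - pos[j, ])^2))
      s1 <- .element_rcov(elem[i], 1) + .element_rcov(elem[j], 1)
      s2 <- .element_rcov(elem[i], 2) + .element_rcov(elem[j], 2)
      s3 <- .element_rcov(elem[i], 3) + .element_rcov(elem[j], 3)
      if (!is.na(s3) && d <= s3 + 0.05) ord[b] <- 3L
      else if (!is.na(s2) && d <= s2 + 0.05) ord[b] <- 2L
      else if (is.na(s2) || is.na(s1) || d >= s1 - 0.05) ord[b] <- 1L
      else cand <- c(cand, b)        # between the double and single bands
    }
  }

  # --- conjugation rule (shared Kekulizer) --------------------------------
  if (length(cand)) {
    cand <- sort(unique(cand))
    cur <- ord; cur[cand] <- 1L   # candidates count 1 toward current valence
    vsum <- .valence_sums(bt, cur, n_atoms(mol))
    hexp <- col_or(mol, "atom", "hexp", "i", -1L)
    spare <- .valence_std(elem, fchg) - vsum - ifelse(hexp > 0L, hexp, 0L)
    arom <- col_or(mol, "atom", "arom", "i", 0L)
    must <- which(arom == 1L & elem == 6L & spare >= 1L)
    elig <- which(spare >= 1L)
    sol <- .kekulize(bt, cand, must, elig)
    if (is.null(sol))
      stop("cannot kekulize conjugated system; offending atoms: ",
           paste(must, collapse = ", "))
    ord[cand] <- ifelse(sol, 2L, 1L)
  }

  # --- valence validation -------------------------------------------------
  vsum <- .valence_sums(bt, ord, n_atoms(mol))
  bad <- which(vsum > .valence_cap(elem, fchg) + pmax(0L, fchg))
  if (length(bad))
    stop("valence contradiction after bond perception at atoms: ",
         paste(bad, collapse = ", "))
  set_col(mol, "bond", "order", "i", ord)
  invisible(mol)
}

.valence_sums <- function(bt, ord, n) {
  v <- numeric(n)
  for (b in seq_len(nrow(bt))) {
    o <- if (ord[b] == 4L) 1.5 else if (ord[b] == 5L) 1L else ord[b]
    v[bt[b, 1]] <- v[bt[b, 1]] + o
    v[bt[b, 2]] <- v[bt[b, 2]] + o
  }
  v
}

# Alternation assignment: choose a set of candidate bonds to promote to
# double such that every "must" atom (aromatic carbon) gets exactly one and
# no atom more than one. Deterministic lowest-index-first backtracking, then
# a greedy alternation pass over optional atoms. Returns logical over cand
# bonds, or NULL when no assignment covers the must atoms.
.kekulize <- function(bt, cand, must, elig) {
  matched <- integer(0)
  chosen <- logical(length(cand))
  cand_i <- bt[cand, 1]; cand_j <- bt[cand, 2]
  solve <- function(matched) {
    left <- setdiff(must, matched)
    if (length(left) == 0L) return(matched)
    a <- min(left)
    ks <- which((cand_i == a | cand_j == a))
    for (k in ks) {
      other <- if (cand_i[k] == a) cand_j[k] else cand_i[k]
      if (other %in% matched || !(other %in% elig)) next
      res <- solve(c(matched, a, other))
      if (!is.null(res)) {
        chosen[k] <<- TRUE
        return(res)
      }
    }
    NULL
  }
  res <- solve(integer(0))
  if (is.null(res) && length(must)) return(NULL)
  matched <- if (is.null(res)) integer(0) else res
  # greedy alternation over the remaining eligible atoms, low bond index first
  for (k in order(cand)) {
    if (chosen[k]) next
    a <- cand_i[k]; b <- cand_j[k]
    if (!(a %in% matched) && !(b %in% matched) && a %in% elig && b %in% elig) {
      chosen[k] <- TRUE
      matched <- c(matched, a, b)
    }
  }
  chosen
}

#' Add missing hydrogen atoms
#'
#' For each heavy atom, hydrogens are added until the standard
#' (charge-adjusted) valence is met, using the stored implicit-H count
#' (`nh`, e.g. from a SMILES read) when present. New atoms are named
#' `H1`, `H2`, ... in creation order, bonded with order 1, related to the
#' heavy atom's residue, and placed at idealized geometry (tetrahedral,
#' trigonal or linear by hybridization) at standard X-H distances.
#' Existing atoms are never moved. Bond orders must be assigned first
#' (run [fixbond()] if needed).
#'
#' @param mol a molecule with elements, positions and integer bond orders.
#' @return the molecule, invisibly.
#' @export
addHs <- function(mol) {
  elem <- col_or(mol, "atom", "element", "i", 0L)
  fchg <- col_or(mol, "atom", "fchg", "i", 0L)
  bt <- bond_table(mol)
  if (nrow(bt) && any(bt[, 3] == 0L))
    stop("addHs requires assigned bond orders; run fixbond() first")
  vsum <- .valence_sums(bt, bt[, 3], n_atoms(mol))
  nh_col <- col_or(mol, "atom", "nh", "i", -1L)
  pos <- positions(mol)
  nbr <- neighbors(mol)
  res_of <- .residue_of_atoms(mol)
  # over-valence check for elements with firm standard valences (hypervalent
  # P/S/metals are exempt; atoms with an explicit nh count are trusted)
  firm <- elem %in% c(1L, 5L, 6L, 7L, 8L, 9L, 17L, 35L, 53L)
  over <- which(firm & vsum > .valence_std(elem, fchg) & nh_col < 0L)
  if (length(over))
    stop("atom ", over[1], " already exceeds its standard valence")
  heavy <- which(elem > 1L)
  hseq <- 0L
  xh <- c(`6` = 1.09, `7` = 1.01, `8` = 0.96, `16` = 1.34, `15` = 1.42, `5` = 1.19)
  for (i in heavy) {
    want <- if (nh_col[i] >= 0L) nh_col[i]
            else max(0L, .valence_std(elem[i], fchg[i]) - as.integer(round(vsum[i])))
    if (want == 0L) next
    maxord <- if (length(nbr[[i]])) {
      bs <- vapply(nbr[[i]], function(j) {
        which((bt[, 1] == i & bt[, 2] == j) | (bt[, 1] == j & bt[, 2] == i))[1]
      }, integer(1))
      max(bt[bs, 3])
    } else 0L
    ndbl <- if (length(nbr[[i]]))
      sum(bt[(bt[, 1] == i | bt[, 2] == i), 3] == 2L) else 0L
    hyb <- if (maxord >= 3L || ndbl >= 2L) "sp"
           else if (maxord == 2L || maxord == 4L) "sp2" else "sp3"
    exist <- nbr[[i]]
    units <- if (length(exist)) {
      u <- pos[exist, , drop = FALSE] - matrix(pos[i, ], length(exist), 3, byrow = TRUE)
      nrm <- sqrt(rowSums(u^2))
      keep <- nrm > 1e-6          # degenerate (coordinate-less) neighbours
      u[keep, , drop = FALSE] / nrm[keep]
    } else matrix(numeric(0), 0, 3)
    dirs <- .h_directions(units, want, hyb)
    blen <- xh[as.character(elem[i])]; if (is.na(blen)) blen <- 1.0
    for (k in seq_len(want)) {
      hseq <- hseq + 1L
      h <- create_object(mol, "atom")
      set_s(h, "name", paste0("H", hseq))
      set_i(h, "element", 1L)
      set_v(h, "position", pos[i, ] + blen * dirs[k, ])
      add_bond(mol, i, h$id, 1L)
      if (res_of[i] > 0) relate(.morf(mol, "resd", res_of[i]), h)
    }
    if (nh_col[i] >= 0L) set_i(.morf(mol, "atom", i), "nh", 0L)
  }
  invisible(mol)
}

.h_directions <- function(units, count, hyb) {
  norm <- function(v) v / sqrt(sum(v^2))
  perp <- function(u) {
    p <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    norm(p - sum(p * u) * u)
  }
  k <- nrow(units)
  if (hyb == "sp") {
    if (k == 0) return(matrix(c(1, 0, 0, -1, 0, 0), 2, 3, byrow = TRUE)[seq_len(count), , drop = FALSE])
    return(matrix(-units[1, ], 1, 3)[rep(1, count), , drop = FALSE])
  }
  if (hyb == "sp2") {
    if (k == 0) {
      ds <- rbind(c(1, 0, 0), c(-0.5, sqrt(3) / 2, 0), c(-0.5, -sqrt(3) / 2, 0))
      return(ds[seq_len(count), , drop = FALSE])
    }
    if (k == 1) {
      u <- units[1, ]; p <- perp(u)
      ds <- rbind(cos(2 * pi / 3) * u + sin(2 * pi / 3) * p,
                  cos(2 * pi / 3) * u - sin(2 * pi / 3) * p)
      return(ds[seq_len(count), , drop = FALSE])
    }
    b <- -colSums(units)
    if (sqrt(sum(b^2)) < 1e-8) b <- perp(norm(units[1, ]))
    return(matrix(norm(b), 1, 3)[rep(1, count), , drop = FALSE])
  }
  # sp3
  ta <- 109.471220634 * pi / 180
  if (k == 0) {
    ds <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) / sqrt(3)
    return(ds[seq_len(count), , drop = FALSE])
  }
  if (k == 1) {
    u <- units[1, ]; p <- perp(u); q <- norm(.cross3(u, p))
    ds <- t(vapply(c(0, 2 * pi / 3, 4 * pi / 3), function(th)
      cos(ta) * u + sin(ta) * (cos(th) * p + sin(th) * q), numeric(3)))
    return(ds[seq_len(count), , drop = FALSE])
  }
  if (k == 2) {
    b <- -(units[1, ] + units[2, ])
    if (sqrt(sum(b^2)) < 1e-8) b <- perp(norm(units[1, ])) else b <- norm(b)
    n <- .cross3(units[1, ], units[2, ])
    if (sqrt(sum(n^2)) < 1e-8) n <- perp(b) else n <- norm(n)
    half <- 54.7356103 * pi / 180
    ds <- rbind(cos(half) * b + sin(half) * n, cos(half) * b - sin(half) * n)
    return(ds[seq_len(count), , drop = FALSE])
  }
  b <- -colSums(units)
  if (sqrt(sum(b^2)) < 1e-8) b <- c(0, 0, 1) else b <- norm(b)
  matrix(b, 1, 3)[rep(1, count), , drop = FALSE]
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}
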