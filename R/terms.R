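#' Enumerate bonded terms
#'
#' Creates angle (`angl`), proper torsion (`tors`) and improper (`oops`)
#' objects from the bond graph: every connected triple i-j-k becomes one
#' angle, every connected quadruple i-j-k-l one proper torsion (unique up
#' to reversal), and an improper is created at each trigonal center (three
#' neighbours and at least one double/aromatic bond), with the center
#' third and the peripheral atoms in ascending id order. Atoms are related
#' to their terms in definition order. Re-invocation never duplicates a
#' term.
#'
#' @param mol a molecule with bonds.
#' @return invisibly, a named integer vector of term counts.
#' @export
enumerate_terms <- function(mol) {
  nbr <- neighbors(mol)
  n <- n_atoms(mol)
  existing <- function(type, arity) {
    adj <- mol$adj[[.adj_key(type, "atom")]]
    if (is.null(adj)) character(0)
    else vapply(adj, function(r) paste(r, collapse = "-"), character(1))
  }
  have_angl <- existing("angl")
  have_tors <- existing("tors")
  have_oops <- existing("oops")
  mk_term <- function(type, atoms) {
    t <- create_object(mol, type)
    for (a in atoms) relate(t, .morf(mol, "atom", a))
    t
  }
  # angles: center j, neighbour pairs i < k
  for (j in seq_len(n)) {
    ns <- sort(nbr[[j]])
    if (length(ns) < 2) next
    for (x in seq_len(length(ns) - 1)) for (y in (x + 1):length(ns)) {
      key <- paste(c(ns[x], j, ns[y]), collapse = "-")
      if (key %in% have_angl) next
      mk_term("angl", c(ns[x], j, ns[y]))
      have_angl <- c(have_angl, key)
    }
  }
  # proper torsions: central bond j-k
  bt <- bond_table(mol)
  for (b in seq_len(nrow(bt))) {
    j <- bt[b, 1]; k <- bt[b, 2]
    for (i in nbr[[j]]) {
      if (i == k) next
      for (l in nbr[[k]]) {
        if (l == j || l == i) next
        quad <- c(i, j, k, l)
        key1 <- paste(quad, collapse = "-")
        key2 <- paste(rev(quad), collapse = "-")
        if (key1 %in% have_tors || key2 %in% have_tors) next
        canon <- if (key1 <= key2) quad else rev(quad)
        mk_term("tors", canon)
        have_tors <- c(have_tors, paste(canon, collapse = "-"))
      }
    }
  }
  # impropers at trigonal centers
  ord_of <- function(i, j) {
    b <- which((bt[, 1] == i & bt[, 2] == j) | (bt[, 1] == j & bt[, 2] == i))[1]
    if (is.na(b)) 0L else bt[b, 3]
  }
  arom <- col_or(mol, "atom", "arom", "i", 0L)
  for (c_at in seq_len(n)) {
    ns <- sort(nbr[[c_at]])
    if (length(ns) != 3) next
    ords <- vapply(ns, function(j) ord_of(c_at, j), integer(1))
    if (!(any(ords >= 2L) || arom[c_at] == 1L)) next
    atoms <- c(ns[1], ns[2], c_at, ns[3])
    key <- paste(atoms, collapse = "-")
    if (key %in% have_oops) next
    mk_term("oops", atoms)
    have_oops <- c(have_oops, key)
  }
  invisible(c(angl = mol_count(mol, "angl"), tors = mol_count(mol, "tors"),
              oops = mol_count(mol, "oops")))
}

# term atom-id matrix for a term type (rows in definition order)
.term_atoms <- function(mol, type, arity) {
  nt <- mol_count(mol, type)
  out <- matrix(0L, nt, arity)
  adj <- mol$adj[[.adj_key(type, "atom")]]
  for (t in seq_len(nt)) {
    r <- adj[[t]]
    if (length(r) != arity)
      stop(type, " ", t, " relates ", length(r), " atoms; expected ", arity)
    out[t, ] <- r
  }
  out
}
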