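# Energy evaluation: AMBER bonded forms, direct nonbonded sum with
# minimum-image periodic boundaries, and the Generalized Born polar
# desolvation term.

#' Electrostatic conversion constant
#'
#' `INVCHG2` is the Coulomb conversion constant in kcal.A/(mol.e^2) used
#' by all electrostatic terms, taken as the AMBER charge-unit convention
#' 18.2223^2 = 332.0522 (332.05 at the model's quoted precision; prmtop
#' charges are partial charges multiplied by 18.2223, so that q_i*q_j/r on
#' prmtop charges is directly kcal/mol). [coulomb_constant()] recomputes
#' the constant from first principles, K_e * e^2 * N_A / 1e-10 m / 4184,
#' with CODATA-2018 values by default.
#'
#' @export
INVCHG2 <- 18.2223^2

#' @rdname INVCHG2
#' @export
AMBER_CHARGE_SCALE <- 18.2223

#' @rdname INVCHG2
#' @param ke electrostatic (Coulomb) constant, N m^2 / C^2.
#' @param e elementary charge, C.
#' @param na Avogadro constant, 1/mol.
#' @return kcal.A/(mol.e^2).
#' @export
coulomb_constant <- function(ke = 8.9875517873681764e9,
                             e = 1.602176634e-19,
                             na = 6.02214076e23) {
  ke * e^2 * na / 1e-10 / 4184
}

#' Bonded energies
#'
#' `eval_bond()` computes `sum k (r - r0)^2`, `eval_angl()`
#' `sum k (theta - theta0)^2` and `eval_tors()` / `eval_oops()`
#' `sum (PK / IDIVF) (1 + cos(PN phi - phase))` over the enumerated terms,
#' in kcal/mol, with parameters looked up by the atoms' `type` property.
#' A missing parameter raises an error naming the type tuple.
#'
#' @param mol a molecule with positions, types and enumerated terms.
#' @param ff a force field.
#' @return energy in kcal/mol.
#' @export
eval_bond <- function(mol, ff) {
  bt <- bond_table(mol)
  if (nrow(bt) == 0) return(0)
  pos <- positions(mol)
  ty <- col_of(mol, "atom", "type", "s")
  e <- 0
  for (b in seq_len(nrow(bt))) {
    p <- ff_bond(ff, ty[bt[b, 1]], ty[bt[b, 2]])
    r <- sqrt(sum((pos[bt[b, 1], ] - pos[bt[b, 2], ])^2))
    e <- e + p[["k"]] * (r - p[["r0"]])^2
  }
  e
}

#' @rdname eval_bond
#' @export
eval_angl <- function(mol, ff) {
  ta <- .term_atoms(mol, "angl", 3L)
  if (nrow(ta) == 0) return(0)
  pos <- positions(mol)
  ty <- col_of(mol, "atom", "type", "s")
  e <- 0
  for (t in seq_len(nrow(ta))) {
    p <- ff_angle(ff, ty[ta[t, 1]], ty[ta[t, 2]], ty[ta[t, 3]])
    v1 <- pos[ta[t, 1], ] - pos[ta[t, 2], ]
    v2 <- pos[ta[t, 3], ] - pos[ta[t, 2], ]
    cs <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
    th <- acos(pmin(1, pmax(-1, cs)))
    e <- e + p[["k"]] * (th - p[["theta0"]] * pi / 180)^2
  }
  e
}

.dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- .cross3(b1, b2); n2 <- .cross3(b2, b3)
  m1 <- .cross3(n1, b2 / sqrt(sum(b2^2)))
  atan2(sum(m1 * n2), sum(n1 * n2))
}

.fourier_energy <- function(terms, phi) {
  sum(vapply(terms, function(t)
    (t$pk / t$idivf) * (1 + cos(t$pn * phi - t$phase * pi / 180)), numeric(1)))
}

#' @rdname eval_bond
#' @export
eval_tors <- function(mol, ff) {
  ta <- .term_atoms(mol, "tors", 4L)
  if (nrow(ta) == 0) return(0)
  pos <- positions(mol)
  ty <- col_of(mol, "atom", "type", "s")
  e <- 0
  for (t in seq_len(nrow(ta))) {
    terms <- ff_torsion(ff, ty[ta[t, 1]], ty[ta[t, 2]], ty[ta[t, 3]], ty[ta[t, 4]])
    phi <- .dihedral(pos[ta[t, 1], ], pos[ta[t, 2], ], pos[ta[t, 3], ], pos[ta[t, 4], ])
    e <- e + .fourier_energy(terms, phi)
  }
  e
}

#' @rdname eval_bond
#' @export
eval_oops <- function(mol, ff) {
  ta <- .term_atoms(mol, "oops", 4L)
  if (nrow(ta) == 0) return(0)
  pos <- positions(mol)
  ty <- col_of(mol, "atom", "type", "s")
  e <- 0
  for (t in seq_len(nrow(ta))) {
    p <- ff_improper(ff, ty[ta[t, 1]], ty[ta[t, 2]], ty[ta[t, 3]], ty[ta[t, 4]])
    if (is.null(p)) next   # impropers without parameters contribute nothing
    phi <- .dihedral(pos[ta[t, 1], ], pos[ta[t, 2], ], pos[ta[t, 3], ], pos[ta[t, 4], ])
    e <- e + .fourier_energy(list(p), phi)
  }
  e
}

# 1-2 / 1-3 / 1-4 pair classification from the bond graph
.pair_classes <- function(mol) {
  nbr <- neighbors(mol)
  n <- n_atoms(mol)
  p12 <- new.env(parent = emptyenv())
  p13 <- new.env(parent = emptyenv())
  p14 <- new.env(parent = emptyenv())
  pk <- function(i, j) paste(min(i, j), max(i, j))
  for (i in seq_len(n)) for (j in nbr[[i]]) if (j > i) assign(pk(i, j), TRUE, p12)
  for (j in seq_len(n)) {
    ns <- nbr[[j]]
    if (length(ns) >= 2)
      for (x in seq_len(length(ns) - 1)) for (y in (x + 1):length(ns)) {
        k <- pk(ns[x], ns[y])
        if (is.null(p12[[k]])) assign(k, TRUE, p13)
      }
  }
  bt <- bond_table(mol)
  for (b in seq_len(nrow(bt))) {
    j <- bt[b, 1]; k <- bt[b, 2]
    for (i in nbr[[j]]) {
      if (i == k) next
      for (l in nbr[[k]]) {
        if (l == j || l == i) next
        key <- pk(i, l)
        if (is.null(p12[[key]]) && is.null(p13[[key]])) assign(key, TRUE, p14)
      }
    }
  }
  list(p12 = p12, p13 = p13, p14 = p14, key = pk)
}

#' Direct nonbonded energy
#'
#' Pairwise electrostatic (`INVCHG2 * q_i q_j / r_ij`) and Lennard-Jones
#' 12-6 sum over all pairs j > i, excluding 1-2 and 1-3 pairs and scaling
#' 1-4 pairs by `1/scee` (electrostatics) and `1/scnb` (van der Waals).
#' LJ parameters combine as `Rmin_ij = Rmin/2_i + Rmin/2_j`,
#' `eps_ij = sqrt(eps_i eps_j)`. Under periodic boundaries (`box` given)
#' the minimum-image convention is applied and `cutoff` must be smaller
#' than half the shortest box edge; there is no Ewald summation - the
#' periodic sum is a truncated direct sum.
#'
#' @param mol molecule with `pchg`, `type`, positions and bonds.
#' @param ff force field providing vdW parameters.
#' @param cutoff pair cutoff in Angstrom (default Inf).
#' @param box optional length-3 box edges for minimum-image PBC.
#' @param scee,scnb 1-4 scaling divisors (AMBER defaults 1.2 and 2.0).
#' @return named numeric `c(elec =, vdw =)` in kcal/mol.
#' @export
nonbond_direct <- function(mol, ff, cutoff = Inf, box = NULL,
                           scee = 1.2, scnb = 2.0) {
  n <- n_atoms(mol)
  if (n < 2) return(c(elec = 0, vdw = 0))
  pos <- positions(mol)
  q <- col_or(mol, "atom", "pchg", "d", 0)
  ty <- col_of(mol, "atom", "type", "s")
  utypes <- unique(ty)
  vdw <- lapply(utypes, function(t) ff_vdw(ff, t))
  names(vdw) <- utypes
  rmin2 <- unname(vapply(ty, function(t) vdw[[t]][["rmin2"]], numeric(1)))
  eps <- unname(vapply(ty, function(t) vdw[[t]][["eps"]], numeric(1)))
  if (!is.null(box)) {
    box <- as.numeric(box)
    if (is.finite(cutoff) && cutoff >= min(box) / 2)
      stop("cutoff must be smaller than half the shortest box edge")
  }
  cls <- .pair_classes(mol)
  elec <- 0; vdwE <- 0
  for (i in seq_len(n - 1)) {
    jj <- (i + 1):n
    dv <- pos[jj, , drop = FALSE] - matrix(pos[i, ], length(jj), 3, byrow = TRUE)
    if (!is.null(box))
      dv <- dv - sweep(round(sweep(dv, 2, box, `/`)), 2, box, `*`)
    r <- sqrt(rowSums(dv^2))
    for (m in seq_along(jj)) {
      j <- jj[m]
      key <- cls$key(i, j)
      if (!is.null(cls$p12[[key]]) || !is.null(cls$p13[[key]])) next
      if (r[m] > cutoff) next
      we <- 1; wv <- 1
      if (!is.null(cls$p14[[key]])) { we <- 1 / scee; wv <- 1 / scnb }
      elec <- elec + we * INVCHG2 * q[i] * q[j] / r[m]
      rm <- rmin2[i] + rmin2[j]
      ep <- sqrt(eps[i] * eps[j])
      if (ep > 0) {
        sr6 <- (rm / r[m])^6
        vdwE <- vdwE + wv * ep * (sr6^2 - 2 * sr6)
      }
    }
  }
  c(elec = unname(elec), vdw = unname(vdwE))
}

#' Generalized Born polar solvation energy
#'
#' Computes the GB polar desolvation energy
#' \deqn{E_{GB} = -INVCHG2 (1 - 1/\epsilon) \sum_{i<j} q_i q_j / f_{GB}}
#' with \eqn{f_{GB} = [r_{ij}^2 + \alpha_{ij}^2 \exp(-r_{ij}^2 /
#' (2\alpha_{ij}^2))]^{1/2}} and \eqn{\alpha_{ij}^2 = \alpha_i \alpha_j}.
#' The sum runs over distinct pairs j > i exactly as the model prints it:
#' no self-energy term and no bonded exclusions. `variant = "standard"`
#' switches the exponent denominator to the literature-common
#' \eqn{4\alpha_i\alpha_j}. Born radii come from the `born` atom property
#' when present, otherwise from a packaged mbondi-like per-element table.
#'
#' @param mol molecule with charges (`pchg`) and positions.
#' @param epsilon solvent dielectric constant (water, default 78.5).
#' @param variant `"as_printed"` (exponent 2 alpha_ij^2) or `"standard"`.
#' @param born optional numeric vector of per-atom Born radii (Angstrom).
#' @return E_GB in kcal/mol (non-positive for like defaults).
#' @export
nonbond_egb <- function(mol, epsilon = 78.5,
                        variant = c("as_printed", "standard"), born = NULL) {
  variant <- match.arg(variant)
  n <- n_atoms(mol)
  if (n < 2) return(0)
  q <- col_or(mol, "atom", "pchg", "d", NA_real_)
  if (anyNA(q))
    stop("missing partial charge on atom(s) ", paste(which(is.na(q)), collapse = ", "))
  if (is.null(born)) {
    born <- col_or(mol, "atom", "born", "d", NA_real_)
    miss <- is.na(born)
    if (any(miss)) {
      elem <- col_or(mol, "atom", "element", "i", 0L)
      born[miss] <- element_born(elem[miss])
    }
  }
  if (any(!is.finite(born) | born <= 0))
    stop("invalid Born radius on atom(s) ",
         paste(which(!is.finite(born) | born <= 0), collapse = ", "))
  pos <- positions(mol)
  e <- 0
  denomf <- if (variant == "as_printed") 2 else 4
  for (i in seq_len(n - 1)) {
    jj <- (i + 1):n
    dv <- pos[jj, , drop = FALSE] - matrix(pos[i, ], length(jj), 3, byrow = TRUE)
    r2 <- rowSums(dv^2)
    ab <- born[i] * born[jj]
    fgb <- sqrt(r2 + ab * exp(-r2 / (denomf * ab)))
    e <- e + sum(q[i] * q[jj] / fgb)
  }
  -INVCHG2 * (1 - 1 / epsilon) * e
}

#' Full energy report
#'
#' Evaluates all bonded terms, the direct nonbonded sum and (optionally)
#' the GB solvation term, and returns them with their total.
#'
#' @inheritParams nonbond_direct
#' @param gb include the Generalized Born term (default TRUE when charges
#'   are present).
#' @param epsilon GB solvent dielectric.
#' @return object of class `"energy_report"` (also a named list).
#' @export
energy_report <- function(mol, ff, cutoff = Inf, box = NULL, gb = TRUE,
                          epsilon = 78.5) {
  nb <- nonbond_direct(mol, ff, cutoff = cutoff, box = box)
  out <- list(bond = eval_bond(mol, ff), angle = eval_angl(mol, ff),
              torsion = eval_tors(mol, ff), improper = eval_oops(mol, ff),
              elec_direct = unname(nb["elec"]), vdw = unname(nb["vdw"]),
              egb = if (gb) nonbond_egb(mol, epsilon = epsilon) else 0)
  out$total <- sum(unlist(out))
  class(out) <- "energy_report"
  out
}

#' @export
print.energy_report <- function(x, ...) {
  cat("energy (kcal/mol):\n")
  for (k in setdiff(names(x), "total"))
    cat(sprintf("  %-12s %14.6f\n", k, x[[k]]))
  cat(sprintf("  %-12s %14.6f\n", "total", x$total))
  invisible(x)
}

#' @export
as.data.frame.energy_report <- function(x, ...) {
  data.frame(term = names(unclass(x)), energy = unlist(unclass(x)),
             row.names = NULL)
}
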