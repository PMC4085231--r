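#' Rigid-body transforms and centers
#'
#' `mol_translate()` shifts all atom positions by a vector,
#' `mol_transform()` applies a 3x3 matrix plus optional translation,
#' `mol_rotate()` rotates about an axis through a given origin (Rodrigues
#' rotation), and `mol_center()` returns the unweighted geometric mean of
#' the member-atom positions of a molecule or a residue handle.
#' `mass_center()` is the mass-weighted variant, clearly distinct.
#'
#' @param mol a molecule with atom positions.
#' @param v numeric length-3 translation vector (Angstrom).
#' @export
mol_translate <- function(mol, v) {
  stopifnot(length(v) == 3)
  p <- positions(mol)
  if (nrow(p) == 0) stop("empty selection: molecule has no atoms")
  set_positions(mol, sweep(p, 2, as.numeric(v), `+`))
  invisible(mol)
}

#' @rdname mol_translate
#' @param m 3x3 transform matrix (orthonormal for rigid-body use).
#' @param shift translation applied after the matrix.
#' @export
mol_transform <- function(mol, m, shift = c(0, 0, 0)) {
  stopifnot(is.matrix(m), all(dim(m) == c(3, 3)))
  p <- positions(mol)
  if (nrow(p) == 0) stop("empty selection: molecule has no atoms")
  set_positions(mol, sweep(p %*% t(m), 2, as.numeric(shift), `+`))
  invisible(mol)
}

#' @rdname mol_translate
#' @param axis rotation axis (any nonzero length-3 vector).
#' @param angle rotation angle in degrees.
#' @param origin point the axis passes through (default the origin).
#' @export
mol_rotate <- function(mol, axis, angle, origin = c(0, 0, 0)) {
  u <- as.numeric(axis)
  nu <- sqrt(sum(u^2))
  if (nu == 0) stop("rotation axis must be nonzero")
  u <- u / nu
  th <- angle * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  p <- positions(mol)
  if (nrow(p) == 0) stop("empty selection: molecule has no atoms")
  p0 <- sweep(p, 2, as.numeric(origin))
  set_positions(mol, sweep(p0 %*% t(R), 2, as.numeric(origin), `+`))
  invisible(mol)
}

#' @rdname mol_translate
#' @param target a molecule or a residue handle.
#' @return `mol_center` / `mass_center`: numeric length-3 center (Angstrom).
#' @export
mol_center <- function(target) {
  p <- .target_positions(target)
  if (nrow(p$pos) == 0) stop("empty selection: no atoms to center")
  colMeans(p$pos)
}

#' @rdname mol_translate
#' @export
mass_center <- function(target) {
  p <- .target_positions(target)
  if (nrow(p$pos) == 0) stop("empty selection: no atoms to center")
  w <- element_mass(p$elem)
  if (sum(w) == 0) w <- rep(1, length(w))
  colSums(p$pos * w) / sum(w)
}

.target_positions <- function(target) {
  if (is_molecule(target)) {
    pos <- positions(target)
    elem <- col_or(target, "atom", "element", "i", 0L)
  } else if (inherits(target, "morf") && target$type == "resd") {
    ids <- related_ids(target, "atom")
    pos <- positions(target$mol)[ids, , drop = FALSE]
    elem <- col_or(target$mol, "atom", "element", "i", 0L)[ids]
  } else stop("center target must be a molecule or a residue handle")
  list(pos = pos, elem = elem)
}
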