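# Property storage: per-type columnar tables keyed by base-40 name hashes.
# Five kinds mirror the accessor family: i (integer), d (double), s (string),
# v (numeric vector, stored flat), a (any R value; excluded from file IO).

.col_key <- function(key) {
  if (is.numeric(key)) format(key, scientific = FALSE, trim = TRUE)
  else format(encode_name(key), scientific = FALSE, trim = TRUE)
}

.get_col <- function(mol, type, key) {
  cmp <- mol$cmp[[type]]
  if (is.null(cmp)) return(NULL)
  cmp$cols[[.col_key(key)]]
}

.make_col <- function(mol, type, key, kind, width = 0L) {
  .ensure_cmp(mol, type)
  cmp <- mol$cmp[[type]]
  k <- .col_key(key)
  col <- cmp$cols[[k]]
  if (!is.null(col)) {
    if (col$kind != kind)
      stop("property '", key, "' on ", type, " already exists with kind '",
           col$kind, "', not '", kind, "'")
    return(col)
  }
  name <- if (is.character(key)) key else NA_character_
  data <- if (kind == "a") vector("list", cmp$n)
          else rep(.col_default(kind, width),
                   if (kind == "v") 1L else cmp$n)
  if (kind == "v") data <- numeric(width * cmp$n)
  col <- list(name = name, kind = kind, width = as.integer(width), data = data)
  cmp$cols[[k]] <- col
  mol$cmp[[type]] <- cmp
  col
}

.set_prop <- function(h, key, value, kind) {
  .check_handle(h)
  mol <- h$mol
  width <- if (kind == "v") length(value) else 0L
  col <- .make_col(mol, h$type, key, kind, width)
  k <- .col_key(key)
  if (kind == "v") {
    if (length(value) != col$width)
      stop("vector property '", key, "' has width ", col$width,
           ", got length ", length(value))
    off <- (h$id - 1L) * col$width
    col$data[off + seq_len(col$width)] <- as.numeric(value)
  } else if (kind == "a") {
    col$data[[h$id]] <- value
  } else {
    col$data[h$id] <- switch(kind, i = as.integer(value),
                             d = as.numeric(value), s = as.character(value))
  }
  mol$cmp[[h$type]]$cols[[k]] <- col
  invisible(h)
}

.get_prop <- function(h, key, kind, must = TRUE) {
  .check_handle(h)
  col <- .get_col(h$mol, h$type, key)
  if (is.null(col)) {
    if (must) stop("missing property '", key, "' on ", h$type, " ", h$id)
    return(list(found = FALSE, value = NULL))
  }
  if (col$kind != kind)
    stop("property '", key, "' has kind '", col$kind, "', requested '", kind, "'")
  value <- if (kind == "v") {
    off <- (h$id - 1L) * col$width
    col$data[off + seq_len(col$width)]
  } else if (kind == "a") col$data[[h$id]] else col$data[h$id]
  if (must) value else list(found = TRUE, value = value)
}

#' Set and get molecular-object properties
#'
#' The accessor family `set_i`/`get_i` (integer), `set_d`/`get_d` (double),
#' `set_s`/`get_s` (string), `set_v`/`get_v` (numeric vector, stored as a
#' flat 1-D array per column) and `set_a`/`get_a` (any R value). Columns are
#' created lazily on first set, with default fill (0, 0.0, "", zero vector,
#' NULL) for pre-existing objects. Keys may be property names or their
#' base-40 hashes (see [encode_name()]). `try_prop()` is the two-result
#' form: it returns `list(found =, value =)` instead of failing on an
#' absent key.
#'
#' @param h an object handle.
#' @param key property name (character) or hash (numeric).
#' @param value the value to store.
#' @name properties
NULL

#' @rdname properties
#' @export
set_i <- function(h, key, value) .set_prop(h, key, value, "i")
#' @rdname properties
#' @export
set_d <- function(h, key, value) .set_prop(h, key, value, "d")
#' @rdname properties
#' @export
set_s <- function(h, key, value) .set_prop(h, key, value, "s")
#' @rdname properties
#' @export
set_v <- function(h, key, value) .set_prop(h, key, value, "v")
#' @rdname properties
#' @export
set_a <- function(h, key, value) .set_prop(h, key, value, "a")
#' @rdname properties
#' @export
get_i <- function(h, key) .get_prop(h, key, "i")
#' @rdname properties
#' @export
get_d <- function(h, key) .get_prop(h, key, "d")
#' @rdname properties
#' @export
get_s <- function(h, key) .get_prop(h, key, "s")
#' @rdname properties
#' @export
get_v <- function(h, key) .get_prop(h, key, "v")
#' @rdname properties
#' @export
get_a <- function(h, key) .get_prop(h, key, "a")

#' @rdname properties
#' @param kind one of `"i"`, `"d"`, `"s"`, `"v"`, `"a"`.
#' @export
try_prop <- function(h, key, kind) .get_prop(h, key, kind, must = FALSE)

#' Whole-column access
#'
#' `col_of` returns the full property column of a type (a matrix with one
#' row per object for vector columns); it errors if the column is absent.
#' `col_or` returns `default` repeated when the column is absent.
#' `set_col` replaces a full column.
#'
#' @param mol a molecule.
#' @param type a type code.
#' @param key property name or hash.
#' @param kind property kind character.
#' @param default per-object default used by `col_or`.
#' @export
col_of <- function(mol, type, key, kind) {
  col <- .get_col(mol, type, key)
  if (is.null(col)) stop("missing property column '", key, "' on ", type)
  if (col$kind != kind)
    stop("property '", key, "' has kind '", col$kind, "', requested '", kind, "'")
  if (kind == "v") matrix(col$data, ncol = col$width, byrow = TRUE)
  else col$data
}

#' @rdname col_of
#' @export
col_or <- function(mol, type, key, kind, default) {
  col <- .get_col(mol, type, key)
  n <- mol_count(mol, type)
  if (is.null(col)) {
    if (kind == "v") return(matrix(rep(default, each = n), nrow = n))
    return(rep(default, n))
  }
  col_of(mol, type, key, kind)
}

#' @rdname col_of
#' @param value replacement column (vector of length n, or n-row matrix for
#'   kind `"v"`).
#' @export
set_col <- function(mol, type, key, kind, value) {
  n <- mol_count(mol, type)
  if (kind == "v") {
    value <- as.matrix(value)
    stopifnot(nrow(value) == n)
    col <- .make_col(mol, type, key, kind, ncol(value))
    if (col$width != ncol(value)) stop("vector column width mismatch")
    col$data <- as.numeric(t(value))
  } else {
    stopifnot(length(value) == n)
    col <- .make_col(mol, type, key, kind)
    col$data <- switch(kind, i = as.integer(value), d = as.numeric(value),
                       s = as.character(value), a = as.list(value))
  }
  mol$cmp[[type]]$cols[[.col_key(key)]] <- col
  invisible(mol)
}

#' Atom coordinates
#'
#' Positions are stored as the flat vector property `"position"` (width 3,
#' Angstrom). `positions()` returns them as an n x 3 matrix.
#'
#' @param mol a molecule.
#' @export
positions <- function(mol) {
  n <- n_atoms(mol)
  if (n == 0L) return(matrix(numeric(0), ncol = 3))
  col_or(mol, "atom", "position", "v", c(0, 0, 0))
}

#' @rdname positions
#' @param value n x 3 numeric matrix.
#' @export
set_positions <- function(mol, value) {
  set_col(mol, "atom", "position", "v", value)
}
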