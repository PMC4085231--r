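#' Molecule database
#'
#' A simple name-keyed store of molecules, used by the multi-molecule file
#' loader and the command interpreter.
#'
#' @return `new_database()` returns an empty object of class `"mdb"`.
#' @export
new_database <- function() {
  db <- new.env(parent = emptyenv())
  db$entries <- list()
  class(db) <- "mdb"
  db
}

#' @rdname new_database
#' @param db a database.
#' @param name molecule name (non-empty); an existing entry is overwritten.
#' @param mol a molecule.
#' @export
db_put <- function(db, name, mol) {
  stopifnot(inherits(db, "mdb"), is_molecule(mol))
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("database key must be a non-empty name")
  db$entries[[name]] <- mol
  invisible(db)
}

#' @rdname new_database
#' @export
db_get_mol <- function(db, name) {
  stopifnot(inherits(db, "mdb"))
  mol <- db$entries[[name]]
  if (is.null(mol)) stop("molecule '", name, "' not found in database")
  mol
}

#' @rdname new_database
#' @export
db_names <- function(db) names(db$entries)

#' @rdname new_database
#' @export
db_size <- function(db) length(db$entries)

#' @export
print.mdb <- function(x, ...) {
  cat(sprintf("molecule database: %d entries\n", db_size(x)))
  if (db_size(x)) cat(" ", paste(db_names(x), collapse = ", "), "\n")
  invisible(x)
}
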