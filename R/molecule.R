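#' Create an empty relational molecule
#'
#' A molecule owns one component table per molecular-object type (atoms,
#' bonds, residues, angles, ...) and a set of adjacency tables recording
#' relations between object types. There is no nesting: residues do not
#' contain atoms; a residue-atom relation is just a row in an adjacency
#' table. The molecule is a mutable reference object (an environment), so
#' all modifying operations update it in place.
#'
#' @param name molecule name (used as the database key and in file titles).
#' @return an object of class `"molecule"`.
#' @export
new_molecule <- function(name = "") {
  mol <- new.env(parent = emptyenv())
  mol$name <- name
  mol$cmp <- list()    # type -> list(n = count, cols = list(hashkey -> column))
  mol$adj <- list()    # "src.dst" -> list of integer vectors, one per source object
  mol$props <- list()  # molecule-level properties (box metadata, SDF data fields)
  class(mol) <- "molecule"
  mol
}

is_molecule <- function(x) inherits(x, "molecule")

.ensure_cmp <- function(mol, type) {
  if (is.null(mol$cmp[[type]]))
    mol$cmp[[type]] <- list(n = 0L, cols = list())
  invisible(mol)
}

#' Count objects of a type
#' @param mol a molecule.
#' @param type a registered type code.
#' @return integer count (constant time).
#' @export
mol_count <- function(mol, type) {
  .check_type(type)
  cmp <- mol$cmp[[type]]
  if (is.null(cmp)) 0L else cmp$n
}

#' @rdname mol_count
#' @export
n_atoms <- function(mol) mol_count(mol, "atom")

#' @rdname mol_count
#' @export
n_bonds <- function(mol) mol_count(mol, "bond")

#' @rdname mol_count
#' @export
n_residues <- function(mol) mol_count(mol, "resd")

# ---- object handles -------------------------------------------------------

#' Object handles
#'
#' A handle is a lightweight `(molecule, type, id)` reference used for all
#' creation, mutation and traversal; it holds no property data itself. Ids
#' are 1-based, matching the external numbering used by the mask language.
#'
#' @param mol a molecule.
#' @param type a registered type code.
#' @param id 1-based object id.
#' @return an object of class `"morf"`.
#' @export
handle <- function(mol, type, id) {
  .check_type(type)
  id <- as.integer(id)
  n <- mol_count(mol, type)
  if (is.na(id) || id < 1L || id > n)
    stop("stale or out-of-range handle: ", type, " ", id, " (count ", n, ")")
  structure(list(mol = mol, type = type, id = id), class = "morf")
}

.morf <- function(mol, type, id)
  structure(list(mol = mol, type = type, id = as.integer(id)), class = "morf")

.check_handle <- function(h) {
  if (!inherits(h, "morf")) stop("not an object handle")
  if (h$id < 1L || h$id > mol_count(h$mol, h$type))
    stop("stale or out-of-range handle: ", h$type, " ", h$id)
  invisible(h)
}

#' @export
print.morf <- function(x, ...) {
  cat(sprintf("<%s %d of molecule '%s'>\n", x$type, x$id, x$mol$name))
  invisible(x)
}

#' @export
print.molecule <- function(x, ...) {
  cat(sprintf("molecule '%s': ", x$name))
  cnt <- vapply(type_codes(), function(t) mol_count(x, t), integer(1))
  cnt <- cnt[cnt > 0]
  if (length(cnt) == 0) cat("(empty)\n")
  else cat(paste(sprintf("%d %s", cnt, names(cnt)), collapse = ", "), "\n")
  invisible(x)
}

# ---- creation -------------------------------------------------------------

#' Create a molecular object
#'
#' Appends a new object of the given type to the molecule's component table;
#' every existing property column is extended with a type-appropriate default
#' (0, 0.0, "", zero-vector, NULL), and every adjacency table with this type
#' as source gains an empty relation row.
#'
#' @inheritParams mol_count
#' @return the handle of the new object (id = new count).
#' @export
create_object <- function(mol, type) {
  .check_type(type)
  .ensure_cmp(mol, type)
  cmp <- mol$cmp[[type]]
  cmp$n <- cmp$n + 1L
  if (length(cmp$cols))
    cmp$cols <- lapply(cmp$cols, function(col) {
      col$data <- c(col$data, .col_default(col$kind, col$width))
      col
    })
  mol$cmp[[type]] <- cmp
  pre <- paste0(type, ".")
  for (key in names(mol$adj)) {
    if (startsWith(key, pre))
      mol$adj[[key]][[cmp$n]] <- integer(0)
  }
  .morf(mol, type, cmp$n)
}

.col_default <- function(kind, width = 0L) {
  switch(kind,
    i = 0L, d = 0, s = "", v = numeric(width),
    a = vector("list", 1L),
    stop("unknown property kind '", kind, "'"))
}

# ---- relations ------------------------------------------------------------

.adj_key <- function(src, dst) paste(src, dst, sep = ".")

.ensure_adj <- function(mol, src, dst) {
  key <- .adj_key(src, dst)
  if (is.null(mol$adj[[key]])) {
    n <- mol_count(mol, src)
    mol$adj[[key]] <- replicate(n, integer(0), simplify = FALSE)
  }
  key
}

#' Relate two molecular objects
#'
#' Records the relation in both directions (e.g. atom-bond and bond-atom
#' adjacency rows are both updated). Relations preserve insertion order;
#' relating an already-related pair is a no-op.
#'
#' @param a,b handles belonging to the same molecule.
#' @export
relate <- function(a, b) {
  .check_handle(a); .check_handle(b)
  if (!identical(a$mol, b$mol)) stop("cannot relate objects of different molecules")
  mol <- a$mol
  k1 <- .ensure_adj(mol, a$type, b$type)
  row <- mol$adj[[k1]][[a$id]]
  if (!(b$id %in% row)) mol$adj[[k1]][[a$id]] <- c(row, b$id)
  k2 <- .ensure_adj(mol, b$type, a$type)
  row <- mol$adj[[k2]][[b$id]]
  if (!(a$id %in% row)) mol$adj[[k2]][[b$id]] <- c(row, a$id)
  invisible(NULL)
}

#' Related objects of a handle
#'
#' @param h an object handle.
#' @param type target type code.
#' @return `related_ids` gives the ordered integer ids; `related` the
#'   corresponding list of handles.
#' @export
related_ids <- function(h, type) {
  .check_handle(h); .check_type(type)
  key <- .adj_key(h$type, type)
  adj <- h$mol$adj[[key]]
  if (is.null(adj)) return(integer(0))
  adj[[h$id]]
}

#' @rdname related_ids
#' @export
related <- function(h, type) {
  ids <- related_ids(h, type)
  lapply(ids, function(i) .morf(h$mol, type, i))
}

#' Iterate over objects of a type
#'
#' Iteration over one type never touches any other type (counting atoms does
#' not visit residues); the sequence is ordered by id and supports random
#' access by position.
#'
#' @inheritParams mol_count
#' @return list of handles, in id order.
#' @export
objects <- function(mol, type) {
  n <- mol_count(mol, type)
  lapply(seq_len(n), function(i) .morf(mol, type, i))
}

# ---- deletion -------------------------------------------------------------

#' Delete a molecular object (with cascade)
#'
#' Removes the object, compacts all property columns and purges every
#' adjacency row that references it. Objects whose definition requires the
#' deleted one are cascade-deleted: deleting an atom removes every bond,
#' angle, torsion, improper and cross-term related to it. Remaining ids are
#' renumbered compactly; handles held from before the call may become stale.
#'
#' @param h handle of the object to delete.
#' @export
delete_object <- function(h) {
  .check_handle(h)
  mol <- h$mol
  dead <- stats::setNames(
    lapply(type_codes(), function(t) integer(0)), type_codes())
  dead[[h$type]] <- h$id
  if (h$type == "atom") {
    dep_types <- setdiff(type_codes(), c("atom", "resd"))
    for (dt in dep_types) {
      ids <- related_ids(h, dt)
      if (length(ids)) dead[[dt]] <- union(dead[[dt]], ids)
    }
  }
  # drop atom-atom entries of dying bonds before generic purge
  if (length(dead$bond)) {
    key_aa <- .adj_key("atom", "atom")
    if (!is.null(mol$adj[[key_aa]])) {
      for (b in dead$bond) {
        ats <- mol$adj[[.adj_key("bond", "atom")]][[b]]
        if (length(ats) == 2L) {
          mol$adj[[key_aa]][[ats[1]]] <- setdiff(mol$adj[[key_aa]][[ats[1]]], ats[2])
          mol$adj[[key_aa]][[ats[2]]] <- setdiff(mol$adj[[key_aa]][[ats[2]]], ats[1])
        }
      }
    }
  }
  # old -> new id maps per type
  maps <- list()
  for (t in names(dead)) {
    n <- mol_count(mol, t)
    if (n == 0L) next
    keep <- setdiff(seq_len(n), dead[[t]])
    map <- rep(NA_integer_, n)
    map[keep] <- seq_along(keep)
    maps[[t]] <- map
    if (length(dead[[t]]) == 0L) next
    cmp <- mol$cmp[[t]]
    cmp$cols <- lapply(cmp$cols, function(col) {
      if (col$kind == "v") {
        idx <- as.vector(outer(seq_len(col$width), (keep - 1L) * col$width, `+`))
        col$data <- col$data[sort(idx)]
      } else {
        col$data <- col$data[keep]
      }
      col
    })
    cmp$n <- length(keep)
    mol$cmp[[t]] <- cmp
  }
  # rebuild adjacency tables: drop dead source rows, remap + drop dead targets
  for (key in names(mol$adj)) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    src <- parts[1]; dst <- parts[2]
    rows <- mol$adj[[key]]
    smap <- maps[[src]]; dmap <- maps[[dst]]
    if (!is.null(smap)) rows <- rows[!is.na(smap)]
    if (!is.null(dmap))
      rows <- lapply(rows, function(r) {
        r <- dmap[r]
        r[!is.na(r)]
      })
    mol$adj[[key]] <- rows
  }
  invisible(NULL)
}

# ---- bond conveniences ----------------------------------------------------

#' Add a bond between two atoms
#'
#' Creates a bond object, relates it to both atoms (the insertion order
#' defines the bond's (i, j) orientation) and records the atom-atom
#' adjacency.
#'
#' @param mol a molecule.
#' @param i,j 1-based atom ids.
#' @param order integer bond order (1, 2, 3; 4 = aromatic, 5 = amide).
#' @return the bond handle.
#' @export
add_bond <- function(mol, i, j, order = 1L) {
  a <- handle(mol, "atom", i); b <- handle(mol, "atom", j)
  b0 <- create_object(mol, "bond")
  set_i(b0, "order", as.integer(order))
  relate(b0, a)
  relate(b0, b)
  relate(a, b)
  invisible(b0)
}

#' Bond table of a molecule
#'
#' @param mol a molecule.
#' @return integer matrix with one row per bond and columns `i`, `j`,
#'   `order` (0 if unset).
#' @export
bond_table <- function(mol) {
  nb <- n_bonds(mol)
  out <- matrix(0L, nrow = nb, ncol = 3, dimnames = list(NULL, c("i", "j", "order")))
  if (nb == 0L) return(out)
  adj <- mol$adj[[.adj_key("bond", "atom")]]
  ord <- col_or(mol, "bond", "order", "i", 0L)
  for (b in seq_len(nb)) {
    ats <- adj[[b]]
    if (length(ats) >= 2L) out[b, 1:2] <- ats[1:2]
  }
  out[, 3] <- ord
  out
}

#' Atom neighbour list
#' @param mol a molecule.
#' @return list of integer vectors: for each atom, ids of bonded atoms.
#' @export
neighbors <- function(mol) {
  n <- n_atoms(mol)
  nb <- replicate(n, integer(0), simplify = FALSE)
  bt <- bond_table(mol)
  for (b in seq_len(nrow(bt))) {
    i <- bt[b, 1]; j <- bt[b, 2]
    if (i > 0 && j > 0) {
      nb[[i]] <- c(nb[[i]], j)
      nb[[j]] <- c(nb[[j]], i)
    }
  }
  nb
}
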