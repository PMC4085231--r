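# AMBER-style atom-mask selection language.
#
# Grammar (whitespace insignificant):
#   expr     := or_expr
#   or_expr  := and_expr ('|' and_expr)*
#   and_expr := dist ('&' dist)*
#   dist     := unary (('<' | '>') ('@' | ':') number)*
#   unary    := '!' unary | '(' expr ')' | selector
#   selector := (':' | '@') idlist
#   idlist   := item (',' item)* ; item := number | number-number | name['*']
#
# ':' selects residues, '@' atoms; "expr < @r" keeps atoms within r Angstrom
# of any atom of expr (the core atoms themselves are at distance 0 and are
# included); "expr > @r" is the strict complement; "< :r" / "> :r" work at
# residue granularity (whole residues with any qualifying atom).

#' Parse an atom-mask expression
#'
#' @param text mask expression, e.g. `":1-10"`, `"@4 < @5"`, `"@CA & !:WAT"`.
#' @return a `"mask_node"` parse tree.
#' @export
parse_mask <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  src <- gsub("[[:space:]]+", "", text)
  if (!nzchar(src)) stop("mask parse error: empty expression")
  st <- new.env(parent = emptyenv())
  st$s <- src; st$i <- 1L
  node <- .mask_or(st)
  if (st$i <= nchar(st$s))
    stop("mask parse error at position ", st$i, ": unexpected '",
         substr(st$s, st$i, st$i), "'")
  structure(node, class = "mask_node")
}

.mk_peek <- function(st) if (st$i <= nchar(st$s)) substr(st$s, st$i, st$i) else ""

.mask_or <- function(st) {
  node <- .mask_and(st)
  while (.mk_peek(st) == "|") {
    st$i <- st$i + 1L
    node <- list(kind = "or", a = node, b = .mask_and(st))
  }
  node
}

.mask_and <- function(st) {
  node <- .mask_dist(st)
  while (.mk_peek(st) == "&") {
    st$i <- st$i + 1L
    node <- list(kind = "and", a = node, b = .mask_dist(st))
  }
  node
}

.mask_dist <- function(st) {
  node <- .mask_unary(st)
  while (.mk_peek(st) %in% c("<", ">")) {
    op <- .mk_peek(st); st$i <- st$i + 1L
    gran <- .mk_peek(st)
    if (!gran %in% c("@", ":"))
      stop("mask parse error at position ", st$i,
           ": distance operator needs '@' or ':' granularity")
    st$i <- st$i + 1L
    rest <- substr(st$s, st$i, nchar(st$s))
    m <- regmatches(rest, regexpr("^[0-9]+\\.?[0-9]*", rest))
    if (!length(m) || !nzchar(m))
      stop("mask parse error at position ", st$i, ": non-numeric distance threshold")
    st$i <- st$i + nchar(m)
    node <- list(kind = "dist", core = node, op = op,
                 gran = if (gran == "@") "atom" else "resd",
                 r = as.numeric(m))
  }
  node
}

.mask_unary <- function(st) {
  ch <- .mk_peek(st)
  if (ch == "!") {
    st$i <- st$i + 1L
    return(list(kind = "not", a = .mask_unary(st)))
  }
  if (ch == "(") {
    st$i <- st$i + 1L
    node <- .mask_or(st)
    if (.mk_peek(st) != ")")
      stop("mask parse error at position ", st$i, ": expected ')'")
    st$i <- st$i + 1L
    return(node)
  }
  if (ch == ":" || ch == "@") {
    st$i <- st$i + 1L
    items <- .mask_idlist(st)
    return(list(kind = if (ch == ":") "resd_node" else "atom_node", items = items))
  }
  if (ch == "")
    stop("mask parse error: dangling operator at end of expression")
  stop("mask parse error at position ", st$i, ": unexpected '", ch, "'")
}

.mask_idlist <- function(st) {
  items <- list()
  repeat {
    rest <- substr(st$s, st$i, nchar(st$s))
    m <- regmatches(rest, regexpr("^[0-9]+-[0-9]+", rest))
    if (length(m) && nzchar(m)) {
      lohi <- as.integer(strsplit(m, "-", fixed = TRUE)[[1]])
      if (lohi[1] > lohi[2])
        stop("mask parse error: descending range ", m)
      items[[length(items) + 1L]] <- list(type = "range", lo = lohi[1], hi = lohi[2])
      st$i <- st$i + nchar(m)
    } else {
      m <- regmatches(rest, regexpr("^[0-9]+", rest))
      if (length(m) && nzchar(m)) {
        items[[length(items) + 1L]] <- list(type = "id", id = as.integer(m))
        st$i <- st$i + nchar(m)
      } else {
        m <- regmatches(rest, regexpr("^[A-Za-z_][A-Za-z0-9_'+]*\\*?", rest))
        if (!length(m) || !nzchar(m))
          stop("mask parse error at position ", st$i, ": empty id list")
        items[[length(items) + 1L]] <- list(type = "name", name = m)
        st$i <- st$i + nchar(m)
      }
    }
    if (.mk_peek(st) == ",") st$i <- st$i + 1L else break
  }
  items
}

#' Evaluate a mask against a molecule
#'
#' `match_mask()` returns the ascending atom ids selected by a parse tree
#' (or expression string). An atom qualifies for `"core < @r"` iff its
#' minimum distance to any core atom is at most `r` (core atoms are at
#' distance 0 and therefore included); `">"` selects the strict complement.
#' Residue granularity (`"< :r"`) selects every atom of any residue with a
#' qualifying atom. [mask_atom()] additionally reports the residues any of
#' whose atoms were selected.
#'
#' @param node a `"mask_node"` or mask expression string.
#' @param mol a molecule (positions required only for distance nodes).
#' @return integer vector of selected atom ids, ascending.
#' @export
match_mask <- function(node, mol) {
  if (is.character(node)) node <- parse_mask(node)
  sel <- .mask_eval(node, mol)
  which(sel)
}

#' @rdname match_mask
#' @param expr mask expression string.
#' @export
mask_atom <- function(mol, expr) {
  atoms <- match_mask(expr, mol)
  res_of <- .residue_of_atoms(mol)
  list(atoms = atoms, residues = sort(unique(res_of[atoms][res_of[atoms] > 0])))
}

.mask_eval <- function(node, mol) {
  n <- n_atoms(mol)
  switch(node$kind,
    atom_node = {
      sel <- rep(FALSE, n)
      nm <- col_or(mol, "atom", "name", "s", "")
      for (it in node$items) sel <- sel | .mask_item_atoms(it, n, nm)
      sel
    },
    resd_node = {
      nres <- n_residues(mol)
      rname <- col_or(mol, "resd", "name", "s", "")
      rsel <- rep(FALSE, nres)
      for (it in node$items) rsel <- rsel | .mask_item_atoms(it, nres, rname)
      res_of <- .residue_of_atoms(mol)
      res_of > 0 & rsel[pmax(res_of, 1L)]
    },
    and = .mask_eval(node$a, mol) & .mask_eval(node$b, mol),
    or  = .mask_eval(node$a, mol) | .mask_eval(node$b, mol),
    not = !.mask_eval(node$a, mol),
    dist = {
      core <- .mask_eval(node$core, mol)
      pos <- positions(mol)
      if (n > 0 && is.null(.get_col(mol, "atom", "position")))
        stop("mask distance operator needs atom positions")
      within <- rep(FALSE, n)
      ci <- which(core)
      if (length(ci)) {
        cp <- pos[ci, , drop = FALSE]
        d2 <- outer(rowSums(pos^2), rep(1, length(ci))) +
          outer(rep(1, n), rowSums(cp^2)) - 2 * pos %*% t(cp)
        dmin <- sqrt(pmax(0, apply(d2, 1, min)))
        within <- dmin <= node$r
      }
      sel <- if (node$op == "<") within else !within
      if (node$gran == "resd") {
        res_of <- .residue_of_atoms(mol)
        hit <- unique(res_of[sel & res_of > 0])
        sel <- sel | (res_of %in% hit)
      }
      sel
    },
    stop("unknown mask node kind '", node$kind, "'"))
}

.mask_item_atoms <- function(it, n, names) {
  sel <- rep(FALSE, n)
  if (it$type == "id") {
    if (it$id < 1 || it$id > n) stop("mask id out of range: ", it$id)
    sel[it$id] <- TRUE
  } else if (it$type == "range") {
    if (it$lo < 1 || it$hi > n)
      stop("mask range out of range: ", it$lo, "-", it$hi)
    sel[it$lo:it$hi] <- TRUE
  } else {
    pat <- it$name
    if (endsWith(pat, "*")) {
      sel <- startsWith(names, substr(pat, 1, nchar(pat) - 1L))
    } else {
      sel <- names == pat
    }
  }
  sel
}

#' @export
print.mask_node <- function(x, ...) {
  cat("mask:", .mask_deparse(x), "\n")
  invisible(x)
}

.mask_deparse <- function(node) {
  switch(node$kind,
    atom_node = paste0("@", .items_deparse(node$items)),
    resd_node = paste0(":", .items_deparse(node$items)),
    and = paste0("(", .mask_deparse(node$a), " & ", .mask_deparse(node$b), ")"),
    or  = paste0("(", .mask_deparse(node$a), " | ", .mask_deparse(node$b), ")"),
    not = paste0("!", .mask_deparse(node$a)),
    dist = paste0("(", .mask_deparse(node$core), " ", node$op, " ",
                  if (node$gran == "atom") "@" else ":", node$r, ")"))
}

.items_deparse <- function(items) {
  paste(vapply(items, function(it) switch(it$type,
    id = as.character(it$id),
    range = paste0(it$lo, "-", it$hi),
    name = it$name), character(1)), collapse = ",")
}
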