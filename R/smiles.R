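# SMILES reader: organic-subset atoms, bracket atoms with isotope / charge /
# explicit H, branches, ring closures 0-9 and %nn, bond symbols - = # :,
# aromaticity via lowercase letters. Stereo marks (/ \ @) are parsed and
# ignored with a warning. Implicit hydrogens are recorded as the integer
# property "nh", not as atom objects (addHs realizes them).

.organic_elems <- c(B = 5L, C = 6L, N = 7L, O = 8L, P = 15L, S = 16L,
                    F = 9L, Cl = 17L, Br = 35L, I = 53L)
.arom_elems <- c(b = 5L, c = 6L, n = 7L, o = 8L, p = 15L, s = 16L)

#' Read a SMILES string
#'
#' Builds a relational molecule from a SMILES line notation: atoms carry
#' `element`, aromatic flag `arom`, formal charge `fchg`, isotope `weight`
#' (brackets only) and implicit hydrogen count `nh`; bonds carry integer
#' `order` (aromatic ring bonds are Kekulized to alternating 1/2).
#' Hydrogens written explicitly inside brackets contribute to `nh` and are
#' not created as atoms.
#'
#' @param text a single SMILES string.
#' @return a molecule (no coordinates).
#' @export
read_smiles <- function(text) {
  stopifnot(is.character(text), length(text) == 1L, nzchar(text))
  mol <- new_molecule(text)
  n <- nchar(text)
  i <- 1L
  prev <- NA_integer_
  stack <- integer(0)
  pending <- 0L         # 0 = default bond
  rings <- list()       # digit label -> list(atom, order)
  stereo_warned <- FALSE
  elems <- integer(0); aroms <- integer(0)

  new_atom <- function(elem, arom, fchg = 0L, weight = 0L, hexp = -1L) {
    a <- create_object(mol, "atom")
    set_i(a, "element", elem)
    set_i(a, "arom", arom)
    set_i(a, "fchg", fchg)
    if (weight > 0L) set_i(a, "weight", weight)
    if (hexp >= 0L) set_i(a, "hexp", hexp)
    set_s(a, "name", paste0(element_symbol(elem), a$id))
    elems[a$id] <<- elem; aroms[a$id] <<- arom
    if (!is.na(prev)) {
      ord <- .resolve_order(pending, aroms[prev], arom)
      add_bond(mol, prev, a$id, ord)
    }
    prev <<- a$id
    pending <<- 0L
    a$id
  }

  close_ring <- function(lab) {
    if (is.na(prev)) stop("SMILES parse error at position ", i, ": ring digit before any atom")
    key <- as.character(lab)
    if (is.null(rings[[key]])) {
      rings[[key]] <<- list(atom = prev, order = pending)
    } else {
      open <- rings[[key]]
      rings[[key]] <<- NULL
      ord <- max(open$order, pending)
      ord <- .resolve_order(ord, aroms[open$atom], aroms[prev])
      add_bond(mol, open$atom, prev, ord)
    }
    pending <<- 0L
  }

  while (i <= n) {
    ch <- substr(text, i, i)
    if (ch == "[") {
      close <- regexpr("]", substr(text, i + 1L, n), fixed = TRUE)
      if (close < 0) stop("SMILES parse error at position ", i, ": unclosed bracket")
      body <- substr(text, i + 1L, i + close - 1L)
      spec <- .parse_bracket(body, i)
      if (spec$stereo && !stereo_warned) {
        warning("stereochemistry marks in SMILES are parsed and ignored")
        stereo_warned <- TRUE
      }
      new_atom(spec$elem, spec$arom, spec$fchg, spec$weight, spec$hexp)
      i <- i + close + 1L
    } else if (ch %in% c("/", "\\")) {
      if (!stereo_warned) {
        warning("stereochemistry marks in SMILES are parsed and ignored")
        stereo_warned <- TRUE
      }
      pending <- 1L
      i <- i + 1L
    } else if (ch == "-") { pending <- 1L; i <- i + 1L
    } else if (ch == "=") { pending <- 2L; i <- i + 1L
    } else if (ch == "#") { pending <- 3L; i <- i + 1L
    } else if (ch == ":") { pending <- 4L; i <- i + 1L
    } else if (ch == "(") {
      if (is.na(prev)) stop("SMILES parse error at position ", i, ": branch before any atom")
      stack <- c(stack, prev); i <- i + 1L
    } else if (ch == ")") {
      if (length(stack) == 0) stop("SMILES parse error at position ", i, ": unmatched ')'")
      prev <- stack[length(stack)]; stack <- stack[-length(stack)]
      i <- i + 1L
    } else if (ch == ".") {
      prev <- NA_integer_; pending <- 0L; i <- i + 1L
    } else if (grepl("^[0-9]$", ch)) {
      close_ring(as.integer(ch)); i <- i + 1L
    } else if (ch == "%") {
      lab <- substr(text, i + 1L, i + 2L)
      if (!grepl("^[0-9]{2}$", lab))
        stop("SMILES parse error at position ", i, ": '%' needs two digits")
      close_ring(as.integer(lab)); i <- i + 3L
    } else {
      two <- substr(text, i, i + 1L)
      if (two %in% names(.organic_elems)) {
        new_atom(.organic_elems[[two]], 0L); i <- i + 2L
      } else if (ch %in% names(.organic_elems)) {
        new_atom(.organic_elems[[ch]], 0L); i <- i + 1L
      } else if (ch %in% names(.arom_elems)) {
        new_atom(.arom_elems[[ch]], 1L); i <- i + 1L
      } else {
        stop("SMILES parse error at position ", i, ": unexpected character '", ch, "'")
      }
    }
  }
  if (length(rings))
    stop("SMILES parse error: unclosed ring digit(s) ", paste(names(rings), collapse = ", "))
  if (length(stack)) stop("SMILES parse error: unclosed branch '('")
  .smiles_finish(mol)
  mol
}

.resolve_order <- function(pending, arom_a, arom_b) {
  if (pending > 0L) return(pending)
  if (isTRUE(arom_a == 1L) && isTRUE(arom_b == 1L)) 4L else 1L
}

.parse_bracket <- function(body, pos) {
  rest <- body
  stereo <- grepl("@", rest, fixed = TRUE)
  rest <- gsub("@+", "", rest)
  weight <- 0L
  m <- regmatches(rest, regexpr("^[0-9]+", rest))
  if (length(m) && nzchar(m)) {
    weight <- as.integer(m)
    rest <- sub("^[0-9]+", "", rest)
  }
  m <- regmatches(rest, regexpr("^([A-Z][a-z]?|[a-z])", rest))
  if (!length(m) || !nzchar(m))
    stop("SMILES parse error at position ", pos, ": bracket without element")
  sym <- m
  if (sym %in% names(.arom_elems)) {
    elem <- .arom_elems[[sym]]; arom <- 1L
  } else {
    # try two-letter, fall back to one
    elem <- element_number(sym)
    if (elem == 0L && nchar(sym) == 2L) {
      sym <- substr(sym, 1, 1)
      elem <- element_number(sym)
    }
    if (elem == 0L)
      stop("SMILES parse error at position ", pos, ": unknown element '", sym, "'")
    arom <- 0L
  }
  rest <- sub(paste0("^", sym), "", rest)
  hexp <- 0L
  m <- regmatches(rest, regexpr("^H[0-9]*", rest))
  if (length(m) && nzchar(m)) {
    hexp <- if (nchar(m) == 1L) 1L else as.integer(substr(m, 2, nchar(m)))
    rest <- sub("^H[0-9]*", "", rest)
  }
  fchg <- 0L
  m <- regmatches(rest, regexpr("^(\\++[0-9]*|-+[0-9]*)", rest))
  if (length(m) && nzchar(m)) {
    sign <- if (startsWith(m, "+")) 1L else -1L
    digits <- gsub("[+-]", "", m)
    reps <- nchar(gsub("[0-9]", "", m))
    fchg <- if (nzchar(digits)) sign * as.integer(digits) else sign * reps
    rest <- sub("^(\\++[0-9]*|-+[0-9]*)", "", rest)
  }
  rest <- sub("^:[0-9]+", "", rest)  # atom maps ignored
  if (nzchar(rest))
    stop("SMILES parse error at position ", pos, ": unsupported bracket content '",
         rest, "'")
  list(elem = elem, arom = arom, fchg = fchg, weight = weight,
       hexp = hexp, stereo = stereo)
}

# Kekulize aromatic systems and fill implicit hydrogen counts.
.smiles_finish <- function(mol) {
  nb <- n_bonds(mol)
  elem <- col_or(mol, "atom", "element", "i", 0L)
  fchg <- col_or(mol, "atom", "fchg", "i", 0L)
  if (nb > 0L) {
    bt <- bond_table(mol)
    cand <- which(bt[, 3] == 4L)
    if (length(cand)) {
      ord <- bt[, 3]
      cur <- ord; cur[cand] <- 1L
      vsum <- .valence_sums(bt, cur, n_atoms(mol))
      hexp <- col_or(mol, "atom", "hexp", "i", -1L)
      spare <- .valence_std(elem, fchg) - vsum - ifelse(hexp > 0L, hexp, 0L)
      arom <- col_or(mol, "atom", "arom", "i", 0L)
      must <- which(arom == 1L & elem == 6L & spare >= 1L)
      elig <- which(spare >= 1L)
      sol <- .kekulize(bt, cand, must, elig)
      if (is.null(sol))
        stop("SMILES parse error: aromatic system cannot be Kekulized (atoms ",
             paste(must, collapse = ", "), ")")
      ord[cand] <- ifelse(sol, 2L, 1L)
      set_col(mol, "bond", "order", "i", ord)
    }
  }
  bt <- bond_table(mol)
  vsum <- if (nb > 0L) .valence_sums(bt, bt[, 3], n_atoms(mol)) else numeric(n_atoms(mol))
  hexp <- col_or(mol, "atom", "hexp", "i", -1L)
  nh <- integer(n_atoms(mol))
  for (i in seq_len(n_atoms(mol))) {
    nh[i] <- if (hexp[i] >= 0L) hexp[i]
             else max(0L, .valence_std(elem[i], fchg[i]) - as.integer(round(vsum[i])))
  }
  set_col(mol, "atom", "nh", "i", nh)
  invisible(mol)
}
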