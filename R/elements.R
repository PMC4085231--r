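# Element data used across the package: atomic numbers, masses, standard
# valences, van der Waals radii, covalent radii by bond order (r1/r2/r3, A)
# and mbondi-style Born radii / GB screening factors. Values are the common
# textbook/AMBER ones; the covalent-radius bands back the bond-length rule.

.element_table <- local({
  tab <- read.table(header = TRUE, stringsAsFactors = FALSE, text = "
symbol number mass    valence vdw  r1    r2    r3    born screen
H      1      1.008   1       1.20 0.31  NA    NA    1.30 0.85
B      5      10.81   3       1.92 0.84  0.78  0.73  1.70 0.72
C      6      12.011  4       1.70 0.77  0.67  0.60  1.70 0.72
N      7      14.007  3       1.55 0.71  0.60  0.54  1.55 0.79
O      8      15.999  2       1.52 0.66  0.57  0.53  1.50 0.85
F      9      18.998  1       1.47 0.57  NA    NA    1.50 0.88
Na     11     22.990  1       2.27 1.66  NA    NA    1.50 0.80
Mg     12     24.305  2       1.73 1.41  NA    NA    1.50 0.80
Si     14     28.085  4       2.10 1.11  1.07  1.00  2.10 0.80
P      15     30.974  3       1.80 1.07  1.02  0.94  1.85 0.86
S      16     32.06   2       1.80 1.05  0.94  NA    1.80 0.96
Cl     17     35.45   1       1.75 1.02  NA    NA    1.70 0.80
K      19     39.098  1       2.75 2.03  NA    NA    1.70 0.80
Ca     20     40.078  2       2.31 1.76  NA    NA    1.70 0.80
Fe     26     55.845  3       2.00 1.32  NA    NA    1.70 0.80
Zn     30     65.38   2       2.10 1.22  NA    NA    1.70 0.80
Br     35     79.904  1       1.85 1.20  NA    NA    1.85 0.80
I      53     126.904 1       1.98 1.39  NA    NA    1.98 0.80
")
  rownames(tab) <- tab$symbol
  tab
})

#' Element lookup helpers
#'
#' `element_number()` maps symbols to atomic numbers (case-normalized),
#' `element_symbol()` the reverse; the remaining helpers return per-element
#' constants used by bond perception, hydrogen addition, solvation and GB
#' defaults. Unknown elements fall back to carbon-like defaults with a
#' warning where that matters.
#'
#' @param symbol character vector of element symbols.
#' @param number integer vector of atomic numbers.
#' @name elements
NULL

.norm_symbol <- function(symbol) {
  s <- trimws(symbol)
  paste0(toupper(substr(s, 1, 1)), tolower(substr(s, 2, nchar(s))))
}

#' @rdname elements
#' @export
element_number <- function(symbol) {
  s <- .norm_symbol(symbol)
  out <- .element_table[s, "number"]
  ifelse(is.na(out), 0L, as.integer(out))
}

#' @rdname elements
#' @export
element_symbol <- function(number) {
  idx <- match(number, .element_table$number)
  out <- .element_table$symbol[idx]
  ifelse(is.na(out), "X", out)
}

.elt_field <- function(number, field, default) {
  idx <- match(number, .element_table$number)
  out <- .element_table[[field]][idx]
  out[is.na(out)] <- default
  out
}

#' @rdname elements
#' @export
element_mass <- function(number) .elt_field(number, "mass", 0)

#' @rdname elements
#' @export
element_valence <- function(number) as.integer(.elt_field(number, "valence", 4L))

#' @rdname elements
#' @export
element_vdw <- function(number) .elt_field(number, "vdw", 1.7)

#' @rdname elements
#' @export
element_born <- function(number) .elt_field(number, "born", 1.5)

#' @rdname elements
#' @export
element_screen <- function(number) .elt_field(number, "screen", 0.8)

# covalent radius for a given bond order; NA when the element forms no such bond
.element_rcov <- function(number, order) {
  .elt_field(number, c("r1", "r2", "r3")[order], NA)
}

# element inference from a PDB-style atom name (columns 77-78 blank case)
.element_from_name <- function(name) {
  vapply(name, function(nm) {
    nm <- trimws(nm)
    a <- gsub("[^A-Za-z]", "", nm)
    if (!nzchar(a)) return("X")
    two <- .norm_symbol(substr(a, 1, 2))
    if (nchar(a) >= 2 && two %in% rownames(.element_table) &&
        two %in% c("Cl", "Br", "Na", "Mg", "Zn", "Fe", "Ca", "Si"))
      return(two)
    one <- toupper(substr(a, 1, 1))
    # names like 1HB / HG11: leading digit or H first -> hydrogen
    if (grepl("^[0-9]", nm) && grepl("H", a)) return("H")
    if (one %in% rownames(.element_table)) return(one)
    "X"
  }, character(1), USE.NAMES = FALSE)
}
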