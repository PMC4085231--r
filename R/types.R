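# Package-level registry: molecular-object type codes and command table.
.relmol <- new.env(parent = emptyenv())

.default_types <- c("atom", "bond", "resd", "angl", "tors", "oops", "tor2", "ptor")

.init_registry <- function() {
  .relmol$types <- .default_types
  .relmol$commands <- list()
}

.onLoad <- function(libname, pkgname) {
  .init_registry()
  .register_builtin_commands()
}

#' Encode a short name as a base-40 hash key
#'
#' Names are mapped to integers by scanning characters left to right and
#' updating a running sum: `sum <- sum * 40 + value`, where a lowercase letter
#' contributes its position from `'a'` (a = 0), an uppercase letter its
#' position from `'A'` (A = 0), a digit its numeric value, and an underscore
#' the value 36. Any other character is skipped. The result is the positional
#' base-40 code of the admissible characters, used throughout the package as
#' a fast property/type key.
#'
#' Note that because `'a'`, `'A'` and `'0'` encode to zero, names differing
#' only by such leading characters share a hash (leading zeros); names of
#' equal length never collide.
#'
#' @param name character vector of names; each must contain at least one and
#'   at most ten admissible characters (letters, digits, underscore).
#' @return numeric vector of hash values (exact integers; exact to the last
#'   digit for names of up to 9 admissible characters).
#' @examples
#' encode_name("_")    # 36
#' encode_name("a")    # 0
#' encode_name("ba")   # 40
#' encode_name("atom") # 30972
#' @export
encode_name <- function(name) {
  stopifnot(is.character(name))
  vapply(name, function(s) {
    if (is.na(s)) stop("name must not be NA")
    codes <- utf8ToInt(s)
    vals <- ifelse(codes >= 97L & codes <= 122L, codes - 97L,
            ifelse(codes >= 65L & codes <= 90L,  codes - 65L,
            ifelse(codes >= 48L & codes <= 57L,  codes - 48L,
            ifelse(codes == 95L, 36L, NA_integer_))))
    vals <- vals[!is.na(vals)]
    if (length(vals) == 0L)
      stop("name '", s, "' has no admissible characters (letters, digits, underscore)")
    if (length(vals) > 10L)
      stop("name '", s, "' has more than 10 admissible characters")
    sum <- 0
    for (v in vals) sum <- sum * 40 + v
    sum
  }, numeric(1), USE.NAMES = FALSE)
}

#' Registered molecular-object type codes
#'
#' Eight four-character codes are registered by default: `atom`, `bond`,
#' `resd` (residue), `angl` (angle), `tors` (torsion), `oops` (out-of-plane /
#' improper torsion), `tor2` (torsion-torsion) and `ptor` (pi-torsion).
#' Additional codes (e.g. `"strd"` for DNA strands) can be registered at run
#' time without touching existing code paths.
#'
#' @return character vector of registered codes.
#' @export
type_codes <- function() .relmol$types

#' @rdname type_codes
#' @param code a new four-character code made of letters, digits, underscore.
#' @export
register_type <- function(code) {
  stopifnot(is.character(code), length(code) == 1L)
  if (nchar(code) != 4L || !grepl("^[A-Za-z0-9_]{4}$", code))
    stop("type code must be 4 admissible characters, got '", code, "'")
  if (!code %in% .relmol$types) .relmol$types <- c(.relmol$types, code)
  invisible(code)
}

#' @rdname type_codes
#' @export
type_hashes <- function() {
  h <- encode_name(.relmol$types)
  names(h) <- .relmol$types
  h
}

.check_type <- function(type) {
  if (!is.character(type) || length(type) != 1L || !type %in% .relmol$types)
    stop("unregistered molecular-object type code: '", paste(type, collapse = ","), "'")
  invisible(type)
}
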