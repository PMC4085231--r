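# AMBER-style parameter files: frcmod (headed sections) and parm.dat
# (sequential layout). Atom-type fields in BOND/ANGLE/DIHE/IMPROPER lines
# are fixed two-character columns joined by '-'.

#' Read an AMBER-style force-field parameter file
#'
#' Parses MASS, BOND, ANGLE, DIHE(DRAL), IMPROPER and NONBON sections into
#' lookup tables. Both the frcmod dialect (explicit section headers) and
#' the sequential parm.dat layout (title line, then mass / hydrophilic /
#' bond / angle / dihedral / improper / 10-12 / equivalence / NONBON
#' blocks separated by blank lines) are supported. Multi-term torsions use
#' the negative-periodicity continuation convention. When `base` is given,
#' parsed entries overlay (replace) matching keys of the base field, as an
#' frcmod does.
#'
#' @param file path, connection or text lines.
#' @param text character lines, used if `file` is missing.
#' @param base optional force field to overlay.
#' @return an object of class `"forcefield"` with elements `masses`,
#'   `bonds` (k, r0), `angles` (k, theta0 deg), `torsions` (list of
#'   (idivf, pk, phase deg, pn) terms), `impropers`, `vdw` (rmin2, eps).
#' @export
read_frc <- function(file = NULL, text = NULL, base = NULL) {
  lines <- .input_lines(file, text)
  ff <- if (is.null(base))
    structure(list(masses = list(), bonds = list(), angles = list(),
                   torsions = list(), impropers = list(), vdw = list()),
              class = "forcefield")
  else base
  headers <- c(MASS = "mass", BOND = "bond", ANGL = "angle", ANGLE = "angle",
               DIHE = "dihe", DIHEDRAL = "dihe", IMPR = "impr",
               IMPROPER = "impr", NONB = "nonb", NONBON = "nonb")
  heads <- toupper(trimws(lines)) %in% names(headers)
  if (any(heads)) {
    section <- NULL
    for (k in seq_along(lines)) {
      line <- lines[k]
      t <- toupper(trimws(line))
      if (t %in% names(headers)) { section <- headers[[t]]; next }
      if (!nzchar(trimws(line))) { section <- section; next }
      if (is.null(section)) next  # title line
      ff <- .frc_dispatch(ff, section, line, k)
    }
  } else {
    ff <- .read_parmdat(ff, lines)
  }
  ff
}

.read_parmdat <- function(ff, lines) {
  # sequential layout: title; MASS; blank; hydrophilic types; BOND; blank;
  # ANGLE; blank; DIHE; blank; IMPROPER; blank; 10-12; blank; equivalence;
  # blank; 'MOD4 ... RE' label + NONBON; END
  k <- 2L
  nseq <- c("mass", "hydro", "bond", "angle", "dihe", "impr", "hb",
            "equiv", "nonb")
  si <- 1L
  while (k <= length(lines) && si <= length(nseq)) {
    line <- lines[k]
    if (!nzchar(trimws(line))) { si <- si + 1L; k <- k + 1L; next }
    if (toupper(trimws(line)) == "END") break
    section <- nseq[si]
    if (section == "nonb" && grepl("^\\s*MOD", toupper(line))) { k <- k + 1L; next }
    if (section == "hydro") {
      # the hydrophilic-type list is a single line, not blank-terminated
      si <- si + 1L; k <- k + 1L; next
    }
    if (!section %in% c("hb", "equiv"))
      ff <- .frc_dispatch(ff, section, line, k)
    k <- k + 1L
  }
  ff
}

.frc_num <- function(tokens, want, section, lineno) {
  v <- suppressWarnings(as.numeric(tokens))
  if (length(v) < want || anyNA(v[seq_len(want)]))
    stop("force-field parse error in ", section, " at line ", lineno,
         ": expected ", want, " numeric fields")
  v
}

.frc_dispatch <- function(ff, section, line, lineno) {
  if (section == "mass") {
    t <- strsplit(trimws(line), "\\s+")[[1]]
    if (length(t) < 2) return(ff)
    v <- .frc_num(t[2], 1, "MASS", lineno)
    ff$masses[[t[1]]] <- v[1]
  } else if (section == "bond") {
    ty <- c(trimws(substr(line, 1, 2)), trimws(substr(line, 4, 5)))
    rest <- strsplit(trimws(substr(line, 6, nchar(line))), "\\s+")[[1]]
    v <- .frc_num(rest, 2, "BOND", lineno)
    ff$bonds[[.bond_key(ty[1], ty[2])]] <- c(k = v[1], r0 = v[2])
  } else if (section == "angle") {
    ty <- c(trimws(substr(line, 1, 2)), trimws(substr(line, 4, 5)),
            trimws(substr(line, 7, 8)))
    rest <- strsplit(trimws(substr(line, 9, nchar(line))), "\\s+")[[1]]
    v <- .frc_num(rest, 2, "ANGLE", lineno)
    ff$angles[[.angle_key(ty[1], ty[2], ty[3])]] <- c(k = v[1], theta0 = v[2])
  } else if (section == "dihe") {
    ty <- c(trimws(substr(line, 1, 2)), trimws(substr(line, 4, 5)),
            trimws(substr(line, 7, 8)), trimws(substr(line, 10, 11)))
    rest <- strsplit(trimws(substr(line, 12, nchar(line))), "\\s+")[[1]]
    v <- .frc_num(rest, 4, "DIHE", lineno)
    key <- .torsion_key(ty)
    term <- list(idivf = v[1], pk = v[2], phase = v[3], pn = abs(v[4]))
    prev <- attr(ff$torsions, "open")
    if (!is.null(prev) && identical(prev, key)) {
      ff$torsions[[key]] <- c(ff$torsions[[key]], list(term))
    } else {
      ff$torsions[[key]] <- list(term)
    }
    attr(ff$torsions, "open") <- if (v[4] < 0) key else NULL
  } else if (section == "impr") {
    ty <- c(trimws(substr(line, 1, 2)), trimws(substr(line, 4, 5)),
            trimws(substr(line, 7, 8)), trimws(substr(line, 10, 11)))
    rest <- strsplit(trimws(substr(line, 12, nchar(line))), "\\s+")[[1]]
    v <- .frc_num(rest, 3, "IMPROPER", lineno)
    ff$impropers[[paste(ty, collapse = "-")]] <-
      list(idivf = 1, pk = v[1], phase = v[2], pn = abs(v[3]))
  } else if (section == "nonb") {
    t <- strsplit(trimws(line), "\\s+")[[1]]
    if (length(t) < 3) return(ff)
    v <- .frc_num(t[2:3], 2, "NONBON", lineno)
    ff$vdw[[t[1]]] <- c(rmin2 = v[1], eps = v[2])
  }
  ff
}

.bond_key <- function(a, b) paste(sort(c(a, b)), collapse = "-")
.angle_key <- function(a, b, c) {
  ends <- sort(c(a, c))
  paste(c(ends[1], b, ends[2]), collapse = "-")
}
.torsion_key <- function(ty) {
  fwd <- paste(ty, collapse = "-")
  rev <- paste(rev(ty), collapse = "-")
  if (fwd <= rev) fwd else rev
}

#' Force-field parameter lookup
#'
#' Bond and angle keys are symmetric; torsion keys reversible, with the
#' wildcard `X` matched at the terminal positions (`X-b-c-X`) when no
#' exact entry exists. A missing parameter raises an error naming the
#' type tuple.
#'
#' @param ff a force field from [read_frc()].
#' @param t1,t2,t3,t4 atom type names.
#' @name ff_lookup
NULL

#' @rdname ff_lookup
#' @export
ff_mass <- function(ff, t1) {
  v <- ff$masses[[t1]]
  if (is.null(v)) stop("missing MASS parameter for atom type '", t1, "'")
  v
}

#' @rdname ff_lookup
#' @export
ff_bond <- function(ff, t1, t2) {
  v <- ff$bonds[[.bond_key(t1, t2)]]
  if (is.null(v)) stop("missing BOND parameter for (", t1, ", ", t2, ")")
  v
}

#' @rdname ff_lookup
#' @export
ff_angle <- function(ff, t1, t2, t3) {
  v <- ff$angles[[.angle_key(t1, t2, t3)]]
  if (is.null(v)) stop("missing ANGLE parameter for (", t1, ", ", t2, ", ", t3, ")")
  v
}

#' @rdname ff_lookup
#' @export
ff_torsion <- function(ff, t1, t2, t3, t4) {
  v <- ff$torsions[[.torsion_key(c(t1, t2, t3, t4))]]
  if (is.null(v)) v <- ff$torsions[[.torsion_key(c("X", t2, t3, "X"))]]
  if (is.null(v)) v <- ff$torsions[[.torsion_key(c("X", t3, t2, "X"))]]
  if (is.null(v))
    stop("missing DIHE parameter for (", t1, ", ", t2, ", ", t3, ", ", t4, ")")
  v
}

#' @rdname ff_lookup
#' @export
ff_improper <- function(ff, t1, t2, t3, t4) {
  # third position is the trigonal center; peripherals may permute and X
  # matches any peripheral type
  for (key in names(ff$impropers)) {
    kt <- strsplit(key, "-", fixed = TRUE)[[1]]
    if (kt[3] != t3) next
    perip <- c(t1, t2, t4)
    ok <- FALSE
    for (p in list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                   c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))) {
      cand <- perip[p]
      if (all(kt[c(1, 2, 4)] == cand | kt[c(1, 2, 4)] == "X")) { ok <- TRUE; break }
    }
    if (ok) return(ff$impropers[[key]])
  }
  NULL
}

#' @rdname ff_lookup
#' @export
ff_vdw <- function(ff, t1) {
  v <- ff$vdw[[t1]]
  if (is.null(v)) stop("missing NONBON (vdW) parameter for atom type '", t1, "'")
  v
}

#' @export
print.forcefield <- function(x, ...) {
  cat(sprintf("force field: %d masses, %d bonds, %d angles, %d torsions, %d impropers, %d vdW\n",
              length(x$masses), length(x$bonds), length(x$angles),
              length(x$torsions), length(x$impropers), length(x$vdw)))
  invisible(x)
}
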