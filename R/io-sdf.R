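# MDL MOL/SDF V2000 reader/writer and the multi-molecule database loader.

#' Read an MDL MOL/SDF (V2000) record
#'
#' The atom block yields atoms with `element` and `position`; the bond
#' block bonds with `order` (4 = aromatic, flagged on the atoms); `M  CHG`
#' property lines set formal charges (`fchg`); data fields (`> <tag>`) are
#' stored as molecule-level text properties. V3000 headers are rejected.
#'
#' @inheritParams read_pdb
#' @return a molecule (the first record, for multi-record input).
#' @export
read_sdf <- function(file = NULL, text = NULL) {
  lines <- .input_lines(file, text)
  recs <- .sdf_records(lines)
  if (length(recs) == 0) stop("SDF parse error: empty input")
  .parse_sdf_record(recs[[1]])
}

.sdf_records <- function(lines) {
  if (length(lines) == 0) return(list())
  seps <- grep("^\\$\\$\\$\\$", lines)
  starts <- c(1L, seps + 1L)
  ends <- c(seps - 1L, length(lines))
  keep <- starts <= ends
  recs <- lapply(which(keep), function(k) lines[starts[k]:ends[k]])
  recs[vapply(recs, function(r) any(nzchar(trimws(r))), logical(1))]
}

.parse_sdf_record <- function(lines) {
  if (length(lines) < 4) stop("SDF parse error: truncated record")
  counts <- lines[4]
  if (grepl("V3000", counts)) stop("SDF parse error: V3000 records are not supported")
  na <- suppressWarnings(as.integer(substr(counts, 1, 3)))
  nb <- suppressWarnings(as.integer(substr(counts, 4, 6)))
  if (is.na(na) || is.na(nb)) stop("SDF parse error: bad counts line: ", counts)
  need <- 4 + na + nb
  if (length(lines) < need)
    stop("SDF parse error: counts line promises ", na, " atoms / ", nb,
         " bonds but the blocks are shorter")
  mol <- new_molecule(trimws(lines[1]))
  for (k in seq_len(na)) {
    line <- lines[4 + k]
    x <- suppressWarnings(as.numeric(substr(line, 1, 10)))
    y <- suppressWarnings(as.numeric(substr(line, 11, 20)))
    z <- suppressWarnings(as.numeric(substr(line, 21, 30)))
    sym <- trimws(substr(line, 31, 34))
    if (any(is.na(c(x, y, z)))) {
      t <- strsplit(trimws(line), "\\s+")[[1]]
      if (length(t) < 4) stop("SDF parse error: bad atom line: ", line)
      x <- as.numeric(t[1]); y <- as.numeric(t[2]); z <- as.numeric(t[3])
      sym <- t[4]
    }
    a <- create_object(mol, "atom")
    set_v(a, "position", c(x, y, z))
    set_i(a, "element", element_number(sym))
    set_s(a, "name", paste0(sym, k))
  }
  for (k in seq_len(nb)) {
    line <- lines[4 + na + k]
    i <- suppressWarnings(as.integer(substr(line, 1, 3)))
    j <- suppressWarnings(as.integer(substr(line, 4, 6)))
    o <- suppressWarnings(as.integer(substr(line, 7, 9)))
    if (any(is.na(c(i, j)))) {
      t <- strsplit(trimws(line), "\\s+")[[1]]
      i <- as.integer(t[1]); j <- as.integer(t[2]); o <- as.integer(t[3])
    }
    if (is.na(o)) o <- 1L
    if (i < 1 || j < 1 || i > na || j > na)
      stop("SDF parse error: bond references atom outside the atom block")
    b <- add_bond(mol, i, j, o)
    if (o == 4L) for (at in related(b, "atom")) set_i(at, "arom", 1L)
  }
  rest <- if (length(lines) > need) lines[(need + 1):length(lines)] else character(0)
  k <- 1
  while (k <= length(rest)) {
    line <- rest[k]
    if (startsWith(line, "M  CHG")) {
      t <- strsplit(trimws(substr(line, 7, nchar(line))), "\\s+")[[1]]
      cnt <- as.integer(t[1])
      for (p in seq_len(cnt)) {
        ai <- as.integer(t[2 * p]); ch <- as.integer(t[2 * p + 1])
        set_i(.morf(mol, "atom", ai), "fchg", ch)
      }
    } else if (startsWith(line, "> ")) {
      tag <- sub("^>\\s*<([^>]*)>.*$", "\\1", line)
      vals <- character(0)
      k <- k + 1
      while (k <= length(rest) && nzchar(trimws(rest[k]))) {
        vals <- c(vals, rest[k]); k <- k + 1
      }
      mol$props[[tag]] <- paste(vals, collapse = "\n")
    }
    k <- k + 1
  }
  # single default residue so downstream residue-based code has a partition
  r <- create_object(mol, "resd")
  set_s(r, "name", "LIG")
  set_i(r, "seq", 1L)
  for (i in seq_len(na)) relate(r, .morf(mol, "atom", i))
  mol
}

#' Write an MDL MOL/SDF (V2000) record
#'
#' @inheritParams write_pdb
#' @param data_fields write molecule-level text properties as `> <tag>`
#'   data fields (default TRUE).
#' @export
write_sdf <- function(mol, file = "", data_fields = TRUE) {
  n <- n_atoms(mol)
  pos <- positions(mol)
  el <- col_or(mol, "atom", "element", "i", 0L)
  fchg <- col_or(mol, "atom", "fchg", "i", 0L)
  bt <- bond_table(mol)
  lines <- c(if (nzchar(mol$name)) mol$name else "mol", "  relmol", "",
             sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nrow(bt)))
  for (i in seq_len(n)) {
    lines <- c(lines, sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                              pos[i, 1], pos[i, 2], pos[i, 3], element_symbol(el[i])))
  }
  for (b in seq_len(nrow(bt))) {
    o <- bt[b, 3]; if (o < 1 || o > 8) o <- 1L
    lines <- c(lines, sprintf("%3d%3d%3d  0", bt[b, 1], bt[b, 2], o))
  }
  chg <- which(fchg != 0L)
  while (length(chg)) {
    take <- chg[seq_len(min(8, length(chg)))]
    lines <- c(lines, paste0(sprintf("M  CHG%3d", length(take)),
                             paste(sprintf("%4d%4d", take, fchg[take]), collapse = "")))
    chg <- chg[-seq_len(min(8, length(chg)))]
  }
  lines <- c(lines, "M  END")
  if (data_fields && length(mol$props)) {
    for (tag in names(mol$props)) {
      v <- mol$props[[tag]]
      if (is.character(v) && length(v) == 1)
        lines <- c(lines, sprintf(">  <%s>", tag), v, "")
    }
  }
  lines <- c(lines, "$$$$")
  if (!identical(file, "")) writeLines(lines, file)
  invisible(lines)
}

#' Load a multi-molecule database file
#'
#' Splits a MOL2 or SDF file into records and stores each molecule in a
#' [new_database()] keyed by its name; unnamed records get sequential
#' names, and duplicate names are suffixed `_2`, `_3`, ... with a warning.
#' The OFF format is not supported and errors explicitly.
#'
#' @inheritParams read_pdb
#' @param format one of `"mol2"`, `"sdf"` (or `"off"`, which errors).
#' @return a molecule database.
#' @export
load_mdb <- function(file = NULL, format = c("sdf", "mol2", "off"), text = NULL) {
  format <- match.arg(format)
  if (format == "off")
    stop("the OFF library format is not supported; use mol2 or sdf")
  lines <- .input_lines(file, text)
  recs <- if (format == "sdf") .sdf_records(lines) else .mol2_records(lines)
  db <- new_database()
  seen <- character(0)
  for (k in seq_along(recs)) {
    mol <- if (format == "sdf") .parse_sdf_record(recs[[k]])
           else .parse_mol2_record(recs[[k]])
    nm <- mol$name
    if (!nzchar(nm)) nm <- paste0("mol_", k)
    if (nm %in% seen) {
      base <- nm; idx <- 2L
      while (paste0(base, "_", idx) %in% seen) idx <- idx + 1L
      nm <- paste0(base, "_", idx)
      warning("duplicate molecule name '", base, "' stored as '", nm, "'")
    }
    seen <- c(seen, nm)
    mol$name <- nm
    db_put(db, nm, mol)
  }
  db
}
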