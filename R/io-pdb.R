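#' Read a PDB/ENT file
#'
#' Dispatches on the first four letters of each line. `ATOM`/`HETATM`
#' records become atoms (name, position, element, occupancy, B factor,
#' serial); a new residue is created whenever `(residue_seq, chain)`
#' changes, and related to its atoms; `CONECT` records become bonds; `TER`
#' ends the running residue; all other record types are skipped. Parsing is
#' fixed-column first with a whitespace-token fallback for nonconforming
#' lines. No bonds are inferred when CONECT is absent (see [fixbond()]).
#'
#' @param file path, connection, or character vector of lines (`text =`).
#' @param text character vector of lines, used if `file` is missing.
#' @param name molecule name (default: file base name).
#' @return a molecule.
#' @export
read_pdb <- function(file = NULL, text = NULL, name = NULL) {
  lines <- .input_lines(file, text)
  if (is.null(name))
    name <- if (is.character(file) && length(file) == 1 && file.exists(file))
      sub("\\.(pdb|ent)$", "", basename(file), ignore.case = TRUE) else "mol"
  mol <- new_molecule(name)
  cur_key <- NULL; cur_res <- NULL
  serial_map <- new.env(parent = emptyenv())
  conect <- list()
  for (ln in seq_along(lines)) {
    line <- lines[[ln]]
    rec <- toupper(substr(line, 1, 4))
    if (rec == "ATOM" || rec == "HETA") {
      f <- .parse_pdb_atom(line, ln)
      a <- create_object(mol, "atom")
      set_s(a, "name", f$name)
      set_v(a, "position", f$xyz)
      set_i(a, "element", f$elem)
      set_d(a, "occupancy", f$occ)
      set_d(a, "bfactor", f$bfac)
      set_i(a, "serial", f$serial)
      assign(as.character(f$serial), a$id, envir = serial_map)
      key <- paste(f$resseq, f$chain, sep = "|")
      if (is.null(cur_key) || key != cur_key) {
        cur_res <- create_object(mol, "resd")
        set_s(cur_res, "name", f$resname)
        set_i(cur_res, "seq", f$resseq)
        set_s(cur_res, "chain", f$chain)
        cur_key <- key
      }
      relate(cur_res, a)
    } else if (rec == "TER " || rec == "TER") {
      cur_key <- NULL
    } else if (rec == "CONE") {
      toks <- suppressWarnings(as.integer(strsplit(trimws(substr(line, 7, nchar(line))),
                                                   "\\s+")[[1]]))
      toks <- toks[!is.na(toks)]
      if (length(toks) >= 2) conect[[length(conect) + 1L]] <- toks
    }
    # every other record type is skipped
  }
  seen <- new.env(parent = emptyenv())
  for (cn in conect) {
    i <- mget(as.character(cn[1]), envir = serial_map, ifnotfound = NA)[[1]]
    for (s in cn[-1]) {
      j <- mget(as.character(s), envir = serial_map, ifnotfound = NA)[[1]]
      if (is.na(i) || is.na(j) || i == j) next
      key <- paste(sort(c(i, j)), collapse = "-")
      if (!is.null(seen[[key]])) next
      seen[[key]] <- TRUE
      add_bond(mol, i, j, 1L)
    }
  }
  mol
}

.parse_pdb_atom <- function(line, ln) {
  line <- sprintf("%-80s", line)
  num <- function(s) suppressWarnings(as.numeric(s))
  xyz <- c(num(substr(line, 31, 38)), num(substr(line, 39, 46)),
           num(substr(line, 47, 54)))
  serial <- suppressWarnings(as.integer(substr(line, 7, 11)))
  name <- trimws(substr(line, 13, 16))
  resname <- trimws(substr(line, 18, 20))
  chain <- substr(line, 22, 22)
  resseq <- suppressWarnings(as.integer(substr(line, 23, 26)))
  occ <- num(substr(line, 55, 60)); bfac <- num(substr(line, 61, 66))
  elem_s <- trimws(substr(line, 77, 78))
  if (any(is.na(xyz))) {
    # whitespace-token fallback for nonconforming dialects
    toks <- strsplit(trimws(line), "\\s+")[[1]]
    nums <- suppressWarnings(as.numeric(toks))
    runs <- which(!is.na(nums))
    cand <- runs[runs >= 4]
    ok <- FALSE
    for (s in cand) {
      if (s + 2 <= length(nums) && all(!is.na(nums[s:(s + 2)]))) {
        xyz <- nums[s:(s + 2)]; ok <- TRUE; break
      }
    }
    if (!ok || any(is.na(xyz)))
      stop("malformed ATOM record at line ", ln, ": non-numeric coordinates")
    if (is.na(serial)) serial <- suppressWarnings(as.integer(toks[2]))
    if (!nzchar(name)) name <- toks[3]
  }
  if (!all(is.finite(xyz)))
    stop("malformed ATOM record at line ", ln, ": non-finite coordinates")
  elem <- if (nzchar(elem_s)) element_number(elem_s) else 0L
  if (elem == 0L) elem <- element_number(.element_from_name(name))
  list(serial = if (is.na(serial)) 0L else serial, name = name,
       resname = resname, chain = chain,
       resseq = if (is.na(resseq)) 1L else resseq,
       xyz = xyz, occ = if (is.na(occ)) 1 else occ,
       bfac = if (is.na(bfac)) 0 else bfac, elem = as.integer(elem))
}

#' Write a PDB file
#'
#' Emits fixed-column PDB v3 ATOM records (serials rolling at 99999,
#' residue sequence numbers at 9999), TER, CONECT records for stored bonds,
#' and END. Atom names longer than four characters are truncated with a
#' warning. Reading the output back preserves atom count, names, residue
#' partitioning and coordinates to three decimals.
#'
#' @param mol a molecule whose atoms carry `position` and `name`.
#' @param file path or connection ("" returns the lines invisibly printed).
#' @return invisibly, the character vector of lines.
#' @export
write_pdb <- function(mol, file = "") {
  n <- n_atoms(mol)
  pos <- positions(mol)
  if (n > 0 && is.null(.get_col(mol, "atom", "position")))
    stop("atoms are missing positions; cannot write PDB")
  nm <- col_or(mol, "atom", "name", "s", "")
  elem <- col_or(mol, "atom", "element", "i", 0L)
  occ <- col_or(mol, "atom", "occupancy", "d", 1)
  bf <- col_or(mol, "atom", "bfactor", "d", 0)
  res_of <- .residue_of_atoms(mol)
  rname <- col_or(mol, "resd", "name", "s", "")
  rseq <- col_or(mol, "resd", "seq", "i", 0L)
  rchain <- col_or(mol, "resd", "chain", "s", " ")
  lines <- character(0)
  for (i in seq_len(n)) {
    name <- nm[i]
    if (!nzchar(name)) name <- element_symbol(elem[i])
    if (nchar(name) > 4) {
      warning("atom name '", name, "' truncated to 4 characters")
      name <- substr(name, 1, 4)
    }
    pname <- if (nchar(name) < 4) paste0(" ", sprintf("%-3s", name)) else name
    ri <- res_of[i]
    rn <- if (ri > 0) rname[ri] else "UNK"
    rs <- if (ri > 0 && rseq[ri] > 0) rseq[ri] else max(ri, 1L)
    ch <- if (ri > 0 && nzchar(trimws(rchain[ri]))) substr(rchain[ri], 1, 1) else " "
    es <- element_symbol(elem[i]); if (es == "X") es <- ""
    lines <- c(lines, sprintf(
      "ATOM  %5d %s %-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      (i - 1L) %% 99999L + 1L, pname, substr(rn, 1, 3), ch,
      (rs - 1L) %% 9999L + 1L, pos[i, 1], pos[i, 2], pos[i, 3],
      occ[i], bf[i], es))
  }
  lines <- c(lines, "TER")
  bt <- bond_table(mol)
  if (nrow(bt) > 0) {
    nbr <- neighbors(mol)
    for (i in seq_len(n)) {
      js <- sort(nbr[[i]])
      while (length(js)) {
        take <- js[seq_len(min(4, length(js)))]
        lines <- c(lines, paste0(sprintf("CONECT%5d", i),
                                 paste(sprintf("%5d", take), collapse = "")))
        js <- js[-seq_len(min(4, length(js)))]
      }
    }
  }
  lines <- c(lines, "END")
  if (!identical(file, "")) writeLines(lines, file)
  invisible(lines)
}

# residue id of each atom (0 when unrelated)
.residue_of_atoms <- function(mol) {
  n <- n_atoms(mol)
  out <- integer(n)
  adj <- mol$adj[[.adj_key("resd", "atom")]]
  if (!is.null(adj)) {
    for (r in seq_along(adj)) out[adj[[r]]] <- r
  }
  out
}

.input_lines <- function(file = NULL, text = NULL) {
  if (!is.null(text)) return(text)
  if (is.null(file)) stop("cannot read input: supply a path, connection or text lines")
  if (inherits(file, "connection")) return(readLines(file, warn = FALSE))
  if (is.character(file) && length(file) == 1 && !grepl("\n", file))
    return(readLines(file, warn = FALSE))
  if (is.character(file)) {
    if (length(file) == 1) return(strsplit(file, "\n", fixed = TRUE)[[1]])
    return(file)
  }
  stop("cannot read input: supply a path, connection or text lines")
}
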