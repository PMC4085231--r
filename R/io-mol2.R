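# TRIPOS MOL2 reader/writer. Bond orders are stored as integers internally:
# 1/2/3 as themselves, "ar" (aromatic) as 4, "am" (amide) as 5; fixbond()
# localizes order-4 bonds on demand.

.mol2_order_in <- c("1" = 1L, "2" = 2L, "3" = 3L, "ar" = 4L, "am" = 5L,
                    "du" = 1L, "un" = 1L, "nc" = 0L)
.mol2_order_out <- c("1", "2", "3", "ar", "am")

#' Read a TRIPOS MOL2 file
#'
#' Parses the `@<TRIPOS>MOLECULE`, `ATOM`, `BOND` and (optionally)
#' `SUBSTRUCTURE` sections. Atoms carry `name`, `position`, SYBYL `type`,
#' partial charge `pchg` and `element` (from the SYBYL type); bonds carry
#' `order`; substructure rows become residues related to their atoms.
#' Aromatic bonds additionally set the `arom` flag on their atoms.
#'
#' @inheritParams read_pdb
#' @return a molecule.
#' @export
read_mol2 <- function(file = NULL, text = NULL) {
  lines <- .input_lines(file, text)
  recs <- .mol2_records(lines)
  if (length(recs) == 0) stop("MOL2 parse error: missing @<TRIPOS>MOLECULE section")
  .parse_mol2_record(recs[[1]])
}

.mol2_records <- function(lines) {
  starts <- grep("^@<TRIPOS>MOLECULE", lines)
  if (length(starts) == 0) return(list())
  ends <- c(starts[-1] - 1L, length(lines))
  lapply(seq_along(starts), function(k) lines[starts[k]:ends[k]])
}

.parse_mol2_record <- function(lines) {
  sec <- function(tag) {
    s <- grep(paste0("^@<TRIPOS>", tag, "\\s*$"), lines)
    if (length(s) == 0) return(character(0))
    s <- s[1] + 1L
    e <- grep("^@<TRIPOS>", lines)
    e <- e[e >= s]
    e <- if (length(e)) min(e) - 1L else length(lines)
    if (e < s) return(character(0))
    out <- lines[s:e]
    out[nzchar(trimws(out)) & !startsWith(trimws(out), "#")]
  }
  head <- sec("MOLECULE")
  mol <- new_molecule(if (length(head)) trimws(head[1]) else "mol")
  atoms <- sec("ATOM")
  subst_of <- integer(0); subst_name <- character(0)
  for (line in atoms) {
    t <- strsplit(trimws(line), "\\s+")[[1]]
    if (length(t) < 6) stop("MOL2 parse error: short ATOM line: ", line)
    a <- create_object(mol, "atom")
    set_s(a, "name", t[2])
    set_v(a, "position", as.numeric(t[3:5]))
    set_s(a, "type", t[6])
    set_i(a, "element", element_number(sub("\\..*$", "", t[6])))
    if (length(t) >= 9) set_d(a, "pchg", as.numeric(t[9]))
    subst_of[a$id] <- if (length(t) >= 7) as.integer(t[7]) else 1L
    subst_name[a$id] <- if (length(t) >= 8) t[8] else "RES"
  }
  for (line in sec("BOND")) {
    t <- strsplit(trimws(line), "\\s+")[[1]]
    if (length(t) < 4) stop("MOL2 parse error: short BOND line: ", line)
    ord <- .mol2_order_in[[tolower(t[4])]]
    if (is.null(ord)) ord <- 1L
    b <- add_bond(mol, as.integer(t[2]), as.integer(t[3]), ord)
    if (ord == 4L) {
      for (at in related(b, "atom")) set_i(at, "arom", 1L)
    }
  }
  # residues from substructure ids (SUBSTRUCTURE section names take priority)
  sub_ids <- sort(unique(subst_of))
  rmap <- stats::setNames(seq_along(sub_ids), sub_ids)
  snames <- stats::setNames(rep("", length(sub_ids)), sub_ids)
  for (i in seq_along(subst_of)) snames[[as.character(subst_of[i])]] <- subst_name[i]
  for (line in sec("SUBSTRUCTURE")) {
    t <- strsplit(trimws(line), "\\s+")[[1]]
    if (length(t) >= 2 && t[1] %in% names(snames)) snames[[t[1]]] <- t[2]
  }
  for (sid in sub_ids) {
    r <- create_object(mol, "resd")
    set_s(r, "name", snames[[as.character(sid)]])
    set_i(r, "seq", as.integer(sid))
  }
  for (i in seq_along(subst_of)) {
    r <- .morf(mol, "resd", rmap[[as.character(subst_of[i])]])
    relate(r, .morf(mol, "atom", i))
  }
  mol
}

#' Write a TRIPOS MOL2 file
#'
#' Emits MOLECULE, ATOM, BOND and SUBSTRUCTURE sections; charges are
#' written to four decimals; molecules without residue information get a
#' single default substructure.
#'
#' @inheritParams write_pdb
#' @export
write_mol2 <- function(mol, file = "") {
  n <- n_atoms(mol)
  pos <- positions(mol)
  nm <- col_or(mol, "atom", "name", "s", "")
  ty <- col_or(mol, "atom", "type", "s", "")
  el <- col_or(mol, "atom", "element", "i", 0L)
  q <- col_or(mol, "atom", "pchg", "d", 0)
  res_of <- .residue_of_atoms(mol)
  rname <- col_or(mol, "resd", "name", "s", "")
  bt <- bond_table(mol)
  nres <- max(1L, n_residues(mol))
  lines <- c("@<TRIPOS>MOLECULE", if (nzchar(mol$name)) mol$name else "mol",
             sprintf("%5d %5d %5d 0 0", n, nrow(bt), nres),
             "SMALL", "USER_CHARGES", "", "@<TRIPOS>ATOM")
  for (i in seq_len(n)) {
    name <- if (nzchar(nm[i])) nm[i] else element_symbol(el[i])
    type <- if (nzchar(ty[i])) ty[i] else element_symbol(el[i])
    ri <- if (res_of[i] > 0) res_of[i] else 1L
    rn <- if (res_of[i] > 0 && nzchar(rname[ri])) rname[ri] else "RES"
    lines <- c(lines, sprintf("%7d %-8s %10.4f %10.4f %10.4f %-8s %4d %-8s %10.4f",
                              i, name, pos[i, 1], pos[i, 2], pos[i, 3],
                              type, ri, rn, q[i]))
  }
  lines <- c(lines, "@<TRIPOS>BOND")
  for (b in seq_len(nrow(bt))) {
    ord <- bt[b, 3]
    os <- if (ord >= 1 && ord <= 5) .mol2_order_out[ord] else "1"
    lines <- c(lines, sprintf("%6d %5d %5d %4s", b, bt[b, 1], bt[b, 2], os))
  }
  lines <- c(lines, "@<TRIPOS>SUBSTRUCTURE")
  if (n_residues(mol) > 0) {
    first_at <- vapply(objects(mol, "resd"), function(r) {
      ids <- related_ids(r, "atom")
      if (length(ids)) min(ids) else 1L
    }, integer(1))
    for (r in seq_len(n_residues(mol))) {
      rn <- if (nzchar(rname[r])) rname[r] else "RES"
      lines <- c(lines, sprintf("%6d %-8s %6d RESIDUE", r, rn, first_at[r]))
    }
  } else {
    lines <- c(lines, sprintf("%6d %-8s %6d RESIDUE", 1L, "RES", 1L))
  }
  if (!identical(file, "")) writeLines(lines, file)
  invisible(lines)
}
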