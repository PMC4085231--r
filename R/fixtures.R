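# Self-contained fixture generator: toy molecules with coordinates, types
# and charges, plus a tiny force field that parameterizes all of them.
# Everything is built in code (deterministically), so tests and examples
# need no external downloads.

.fx_build <- function(name, resdefs, bonds) {
  # resdefs: list of list(name=, atoms=data.frame(name,type,elem,q,x,y,z))
  mol <- new_molecule(name)
  for (rd in resdefs) {
    r <- create_object(mol, "resd")
    set_s(r, "name", rd$name)
    set_i(r, "seq", r$id)
    at <- rd$atoms
    for (k in seq_len(nrow(at))) {
      a <- create_object(mol, "atom")
      set_s(a, "name", at$name[k])
      set_s(a, "type", at$type[k])
      set_i(a, "element", as.integer(at$elem[k]))
      set_d(a, "pchg", at$q[k])
      set_v(a, "position", c(at$x[k], at$y[k], at$z[k]))
      relate(r, a)
    }
  }
  for (b in seq_len(nrow(bonds)))
    add_bond(mol, bonds[b, 1], bonds[b, 2], bonds[b, 3])
  mol
}

#' Fixture molecules
#'
#' Small, fully parameterized molecules built in code: a TIP3P-like water,
#' methane, benzene (Kekulized, aromatic flags set), a four-residue
#' glycine-like peptide backbone, the synthetic 216-water cube of
#' [water_box_template()], and single-atom Na+ / Cl- ion templates. All
#' are covered by the tiny force field of [fx_tiny_frc()].
#'
#' @return a molecule (or character lines for `fx_tiny_frc`).
#' @export
fx_water <- function() {
  at <- data.frame(name = c("O", "H1", "H2"), type = c("OW", "HW", "HW"),
                   elem = c(8L, 1L, 1L), q = c(-0.834, 0.417, 0.417),
                   x = c(0, 0.9572, -0.2399872),
                   y = c(0, 0, 0.9266272), z = c(0, 0, 0))
  .fx_build("WAT", list(list(name = "WAT", atoms = at)),
            rbind(c(1L, 2L, 1L), c(1L, 3L, 1L)))
}

#' @rdname fx_water
#' @export
fx_methane <- function() {
  s <- 1.09 / sqrt(3)
  at <- data.frame(
    name = c("C1", "H1", "H2", "H3", "H4"),
    type = c("CT", "HC", "HC", "HC", "HC"),
    elem = c(6L, 1L, 1L, 1L, 1L),
    q = c(-0.4, 0.1, 0.1, 0.1, 0.1),
    x = c(0, s, s, -s, -s), y = c(0, s, -s, s, -s), z = c(0, s, -s, -s, s))
  .fx_build("MTH", list(list(name = "MTH", atoms = at)),
            cbind(1L, 2:5, 1L))
}

#' @rdname fx_water
#' @export
fx_benzene <- function() {
  rc <- 1.397; rh <- 2.477
  th <- (0:5) * pi / 3
  at <- data.frame(
    name = c(paste0("C", 1:6), paste0("H", 1:6)),
    type = c(rep("CA", 6), rep("HA", 6)),
    elem = c(rep(6L, 6), rep(1L, 6)),
    q = c(rep(-0.115, 6), rep(0.115, 6)),
    x = c(rc * cos(th), rh * cos(th)),
    y = c(rc * sin(th), rh * sin(th)),
    z = rep(0, 12))
  bonds <- rbind(
    cbind(1:6, c(2:6, 1L), rep(c(2L, 1L), 3)),   # alternating Kekule ring
    cbind(1:6, 7:12, 1L))
  mol <- .fx_build("BNZ", list(list(name = "BNZ", atoms = at)), bonds)
  for (i in 1:6) set_i(.morf(mol, "atom", i), "arom", 1L)
  mol
}

#' @rdname fx_water
#' @export
fx_peptide <- function() {
  # four glycine-like backbone residues along x, idealized local geometry
  resdefs <- list(); bonds <- NULL
  prevC <- NA_integer_; off <- 0L
  for (r in 1:4) {
    x0 <- (r - 1) * 3.6
    y <- if (r %% 2 == 0) 0.4 else -0.4
    at <- data.frame(
      name = c("N", "H", "CA", "HA1", "HA2", "C", "O"),
      type = c("N", "H", "CT", "H1", "H1", "C", "O"),
      elem = c(7L, 1L, 6L, 1L, 1L, 6L, 8L),
      q = c(-0.45, 0.25, 0.05, 0.05, 0.05, 0.55, -0.50),
      x = x0 + c(0, -0.4, 1.2, 1.4, 1.4, 2.4, 2.6),
      y = y * c(1, 2.2, 1.6, 2.4, 2.4, 0.4, -0.6),
      z = c(0, 0.4, 0.6, 1.5, -0.7, 0.2, 0.6))
    resdefs[[r]] <- list(name = "GLY", atoms = at)
    rb <- rbind(c(1L, 2L, 1L), c(1L, 3L, 1L), c(3L, 4L, 1L), c(3L, 5L, 1L),
                c(3L, 6L, 1L), c(6L, 7L, 2L)) + off
    rb[, 3] <- c(1L, 1L, 1L, 1L, 1L, 2L)
    bonds <- rbind(bonds, rb)
    if (!is.na(prevC)) bonds <- rbind(bonds, c(prevC, off + 1L, 1L))
    prevC <- off + 6L
    off <- off + 7L
  }
  .fx_build("PEP", resdefs, bonds)
}

#' @rdname fx_water
#' @param ion `"Na+"` or `"Cl-"`.
#' @export
fx_ion <- function(ion = c("Na+", "Cl-")) {
  ion <- match.arg(ion)
  mol <- new_molecule(ion)
  r <- create_object(mol, "resd"); set_s(r, "name", ion); set_i(r, "seq", 1L)
  a <- create_object(mol, "atom")
  set_s(a, "name", ion)
  set_s(a, "type", ion)
  set_i(a, "element", if (ion == "Na+") 11L else 17L)
  set_d(a, "pchg", if (ion == "Na+") 1.0 else -1.0)
  set_v(a, "position", c(0, 0, 0))
  relate(r, a)
  mol
}

#' @rdname fx_water
#' @export
fx_tiny_frc <- function() {
  c("tiny fixture force field (frcmod dialect)",
    "MASS",
    "OW 16.00", "HW 1.008", "CT 12.01", "HC 1.008", "CA 12.01", "HA 1.008",
    "N  14.01", "H  1.008", "H1 1.008", "C  12.01", "O  16.00",
    "Na+ 22.99", "Cl- 35.45",
    "",
    "BOND",
    "OW-HW  553.0  0.9572",
    "CT-HC  340.0  1.090",
    "CA-CA  469.0  1.400",
    "CA-HA  367.0  1.080",
    "N -H   434.0  1.010",
    "N -CT  337.0  1.449",
    "CT-H1  340.0  1.090",
    "CT-C   317.0  1.522",
    "C -O   570.0  1.229",
    "C -N   490.0  1.335",
    "",
    "ANGLE",
    "HW-OW-HW   100.0  104.52",
    "HC-CT-HC    35.0  109.50",
    "CA-CA-CA    63.0  120.00",
    "CA-CA-HA    35.0  120.00",
    "H -N -CT    50.0  118.04",
    "H -N -C     50.0  120.00",
    "CT-N -C     50.0  121.90",
    "N -CT-H1    50.0  109.50",
    "N -CT-C     63.0  110.10",
    "H1-CT-H1    35.0  109.50",
    "H1-CT-C     50.0  109.50",
    "CT-C -O     80.0  120.40",
    "CT-C -N     70.0  116.60",
    "O -C -N     80.0  122.90",
    "",
    "DIHE",
    "X -CA-CA-X    4   14.50  180.0  2.",
    "X -N -CT-X    6    1.80    0.0  3.",
    "X -CT-C -X    4    0.80  180.0  2.",
    "X -C -N -X    4   10.00  180.0  2.",
    "",
    "IMPROPER",
    "X -X -C -O    10.5  180.0  2.",
    "X -X -CA-HA    1.1  180.0  2.",
    "",
    "NONBON",
    "OW  1.7683  0.1520",
    "HW  0.0000  0.0000",
    "CT  1.9080  0.1094",
    "HC  1.4870  0.0157",
    "CA  1.9080  0.0860",
    "HA  1.4590  0.0150",
    "N   1.8240  0.1700",
    "H   0.6000  0.0157",
    "H1  1.3870  0.0157",
    "C   1.9080  0.0860",
    "O   1.6612  0.2100",
    "Na+ 1.8680  0.00277",
    "Cl- 2.4700  0.1000")
}

#' Generate the fixture file set
#'
#' Writes PDB/MOL2/SDF renderings of the fixture molecules, the tiny
#' force-field file and a checksum manifest into `output_dir`.
#' Regeneration is deterministic: running twice produces identical
#' checksums.
#'
#' @param output_dir a writable directory (created if missing).
#' @return invisibly, a data frame manifest (file, md5).
#' @export
generate_fixtures <- function(output_dir) {
  if (!dir.exists(output_dir))
    if (!dir.create(output_dir, recursive = TRUE))
      stop("cannot create fixture directory ", output_dir)
  probe <- file.path(output_dir, ".write_test")
  ok <- tryCatch({ writeLines("x", probe); TRUE }, error = function(e) FALSE)
  if (!ok) stop("fixture directory ", output_dir, " is not writable")
  unlink(probe)
  mols <- list(water = fx_water(), methane = fx_methane(),
               benzene = fx_benzene(), peptide = fx_peptide())
  files <- character(0)
  for (nm in names(mols)) {
    m <- mols[[nm]]
    f1 <- file.path(output_dir, paste0(nm, ".pdb")); write_pdb(m, f1)
    f2 <- file.path(output_dir, paste0(nm, ".mol2")); write_mol2(m, f2)
    f3 <- file.path(output_dir, paste0(nm, ".sdf")); write_sdf(m, f3)
    files <- c(files, f1, f2, f3)
  }
  fw <- file.path(output_dir, "watbox216.pdb")
  write_pdb(water_box_template(), fw)
  ffrc <- file.path(output_dir, "tiny.frcmod")
  writeLines(fx_tiny_frc(), ffrc)
  files <- c(files, fw, ffrc)
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  utils::write.csv(manifest, file.path(output_dir, "MANIFEST.csv"),
                   row.names = FALSE)
  invisible(manifest)
}
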