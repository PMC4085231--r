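tiny_ff <- function() read_frc(text = fx_tiny_frc())

test_that("prmtop structure sections are internally consistent", {
  w <- fx_water()
  ff <- tiny_ff()
  enumerate_terms(w)
  prm <- tempfile(fileext = ".prmtop")
  write_amber_prmtop(w, ff, prm)
  s <- read_prmtop_sections(prm)
  p <- as.integer(s$POINTERS)
  expect_equal(p[1], 3L)                       # NATOM
  expect_equal(p[12], 1L)                      # NRES
  expect_equal(p[3] + p[4], n_bonds(w))        # NBONH + MBONA
  expect_equal(s$RESIDUE_LABEL[1], "WAT")
  expect_equal(s$CHARGE, col_of(w, "atom", "pchg", "d") * relmol::AMBER_CHARGE_SCALE,
               tolerance = 1e-7)
  expect_equal(as.integer(s$ATOMIC_NUMBER), c(8L, 1L, 1L))
  expect_equal(s$MASS, c(16, 1.008, 1.008), tolerance = 1e-7)
  expect_equal(length(s$NONBONDED_PARM_INDEX), p[2]^2)
  expect_equal(length(s$EXCLUDED_ATOMS_LIST), sum(as.integer(s$NUMBER_EXCLUDED_ATOMS)))
  expect_error(write_amber_prmtop(new_molecule("empty"), ff), "zero atoms")
})

test_that("coordinate files follow the restart layout and round-trip", {
  w <- fx_water()
  crd <- tempfile(fileext = ".inpcrd")
  write_inpcrd(w, crd)
  lines <- readLines(crd)
  expect_equal(as.integer(trimws(lines[2])), 3L)
  expect_length(lines, 2 + 2)                 # 9 reals at 6 per line -> 2 lines
  back <- read_inpcrd_coords(crd)
  expect_lt(max(abs(back - positions(w))), 5e-8)
  # box metadata adds a trailing box line
  boxed <- fx_water()
  boxed$props$box <- list(dims = c(20, 21, 22))
  linesb <- write_inpcrd(boxed)
  expect_match(linesb[length(linesb)], "20\\.0000000")
})

test_that("write-read-write produces byte-identical files", {
  m <- fx_methane()
  ff <- tiny_ff()
  enumerate_terms(m)
  f1 <- tempfile(); f2 <- tempfile()
  write_amber_prmtop(m, ff, f1)
  # re-writing from the same in-memory system is deterministic
  write_amber_prmtop(m, ff, f2)
  expect_identical(readLines(f1), readLines(f2))
  c1 <- tempfile(); c2 <- tempfile()
  write_inpcrd(m, c1); write_inpcrd(m, c2)
  expect_identical(readLines(c1), readLines(c2))
})

parity_check <- function(mol, label, tol = 1e-4) {
  ff <- tiny_ff()
  enumerate_terms(mol)
  prm <- tempfile(fileext = ".prmtop"); crd <- tempfile(fileext = ".inpcrd")
  write_amber_prmtop(mol, ff, prm)
  write_inpcrd(mol, crd)
  ref <- prmtop_energy(prm, crd)
  nb <- nonbond_direct(mol, ff)
  internal <- list(bond = eval_bond(mol, ff), angle = eval_angl(mol, ff),
                   dihedral = eval_tors(mol, ff) + eval_oops(mol, ff),
                   elec = nb[["elec"]], vdw = nb[["vdw"]])
  for (k in names(internal))
    expect_lt(abs(ref[[k]] - internal[[k]]), tol,
              label = paste(label, k, "parity gap"))
  expect_lt(abs(ref$total - Reduce(`+`, internal)), tol)
  invisible(ref)
}

test_that("energies recomputed from the written prmtop match internal evaluation", {
  parity_check(fx_water(), "water")
  dimer <- merge_mols(list(fx_water(), {
    w2 <- fx_water(); mol_translate(w2, c(3.0, 0.2, 0.1)); w2
  }), name = "dimer")
  parity_check(dimer, "water dimer")
  parity_check(fx_methane(), "methane")
  parity_check(fx_benzene(), "benzene")
  parity_check(fx_peptide(), "peptide")
  # solvated ion with box metadata
  ion <- fx_ion("Cl-")
  solvate_box(ion, water_box_template(nside = 3L), buffer = 5)
  parity_check(ion, "solvated ion")
})
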