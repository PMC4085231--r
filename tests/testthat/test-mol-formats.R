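test_that("PDB reading maps records onto the relational model", {
  lines <- c(
    "REMARK this line is skipped",
    "ATOM      1  O   HOH A   1       0.000   0.000   0.000  1.00  0.00           O",
    "ATOM      2  H1  HOH A   1       0.957   0.000   0.000  1.00  0.00           H",
    "ATOM      3  H2  HOH A   1      -0.240   0.927   0.000  1.00  0.00           H")
  mol <- read_pdb(text = lines)
  expect_equal(n_atoms(mol), 3L)
  expect_equal(n_residues(mol), 1L)
  expect_equal(get_s(handle(mol, "resd", 1), "name"), "HOH")
  expect_equal(length(related_ids(handle(mol, "resd", 1), "atom")), 3L)
  expect_equal(col_of(mol, "atom", "element", "i"), c(8L, 1L, 1L))
  expect_equal(n_atoms(read_pdb(text = character(0))), 0L)
  expect_error(read_pdb(text = "ATOM      1  O   HOH A   1         a       b       c"),
               "line 1")
})

test_that("PDB round-trip preserves atoms, residues and 3-decimal coordinates", {
  mol <- fx_peptide()
  lines <- write_pdb(mol)
  back <- read_pdb(text = lines)
  expect_equal(n_atoms(back), n_atoms(mol))
  expect_equal(n_residues(back), n_residues(mol))
  expect_equal(col_of(back, "atom", "name", "s"), col_of(mol, "atom", "name", "s"))
  expect_lt(max(abs(positions(back) - positions(mol))), 5e-4)
  expect_equal(relmol:::.residue_of_atoms(back), relmol:::.residue_of_atoms(mol))
  long <- new_molecule("x")
  a <- create_object(long, "atom")
  set_s(a, "name", "ABCDE"); set_i(a, "element", 6L); set_v(a, "position", c(0, 0, 0))
  expect_warning(write_pdb(long), "truncated")
})

test_that("MOL2 round-trips atoms, types, charges (4 dp) and aromatic bonds", {
  bz_lines <- write_mol2(fx_benzene())
  bz <- read_mol2(text = bz_lines)
  expect_equal(n_atoms(bz), 12L)
  expect_equal(n_bonds(bz), 12L)
  # hand-written benzene with 6 'ar' ring bonds
  ar <- c("@<TRIPOS>MOLECULE", "benzene", " 6 6 1", "SMALL", "NO_CHARGES",
          "@<TRIPOS>ATOM",
          sprintf("%d C%d %.3f %.3f 0.0 C.ar 1 BNZ %.4f", 1:6,
                  1:6, 1.397 * cos((0:5) * pi / 3), 1.397 * sin((0:5) * pi / 3),
                  rep(-0.115, 6)),
          "@<TRIPOS>BOND",
          sprintf("%d %d %d ar", 1:6, 1:6, c(2:6, 1)))
  mol <- read_mol2(text = ar)
  expect_equal(n_atoms(mol), 6L)
  bt <- bond_table(mol)
  expect_equal(sum(bt[, 3] == 4L), 6L)
  expect_equal(col_of(mol, "atom", "arom", "i"), rep(1L, 6))
  rt <- read_mol2(text = write_mol2(mol))
  expect_equal(bond_table(rt)[, 3], bt[, 3])
  expect_equal(col_of(rt, "atom", "pchg", "d"), rep(-0.115, 6))
  expect_error(read_mol2(text = "no molecule section"), "MOLECULE")
})

test_that("SDF V2000 parses counts, charges and data fields", {
  mth <- fx_methane()
  lines <- write_sdf(mth)
  back <- read_sdf(text = lines)
  expect_equal(n_atoms(back), 5L)
  expect_equal(n_bonds(back), 4L)
  expect_equal(bond_table(back)[, 3], rep(1L, 4))
  # M CHG property line
  chg <- c("ion", "  prog", "",
           "  1  0  0  0  0  0  0  0  0  0999 V2000",
           "    0.0000    0.0000    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0",
           "M  CHG  1   1  -1",
           "M  END")
  mol <- read_sdf(text = chg)
  expect_equal(get_i(handle(mol, "atom", 1), "fchg"), -1L)
  # counts line disagreement and V3000 are rejected
  bad <- chg; bad[4] <- "  9  0  0  0  0  0  0  0  0  0999 V2000"
  expect_error(read_sdf(text = bad), "counts line")
  v3 <- chg; v3[4] <- "  0  0  0  0  0  0  0  0  0  0999 V3000"
  expect_error(read_sdf(text = v3), "V3000")
})

test_that("load_mdb splits multi-record files and disambiguates names", {
  two <- c(write_sdf(fx_methane()), write_sdf(fx_water()))
  db <- load_mdb(text = two, format = "sdf")
  expect_equal(db_size(db), 2L)
  expect_setequal(db_names(db), c("MTH", "WAT"))
  dup <- c(write_sdf(fx_water()), write_sdf(fx_water()))
  expect_warning(db2 <- load_mdb(text = dup, format = "sdf"), "duplicate")
  expect_setequal(db_names(db2), c("WAT", "WAT_2"))
  m2 <- c(write_mol2(fx_water()), write_mol2(fx_methane()))
  dbm <- load_mdb(text = m2, format = "mol2")
  expect_equal(db_size(dbm), 2L)
  expect_error(load_mdb(text = two, format = "off"), "not supported")
})
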