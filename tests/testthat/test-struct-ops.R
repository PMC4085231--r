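test_that("rigid-body transforms preserve internal geometry", {
  set.seed(7)
  for (trial in 1:5) {
    mol <- random_format_mol(trial + 100)
    p0 <- positions(mol)
    d0 <- as.matrix(dist(p0))
    mol_translate(mol, runif(3, -5, 5))
    mol_rotate(mol, runif(3, -1, 1), runif(1, 0, 360), origin = runif(3, -3, 3))
    expect_lt(max(abs(as.matrix(dist(positions(mol))) - d0)), 1e-9)
  }
  mol <- fx_methane()
  p0 <- positions(mol)
  mol_rotate(mol, c(0.3, -1, 2), 360)
  expect_lt(max(abs(positions(mol) - p0)), 1e-9)
})

test_that("center is the unweighted mean; translate shifts it", {
  mol <- new_molecule("m")
  for (x in c(0, 2)) {
    a <- create_object(mol, "atom"); set_i(a, "element", 6L)
    set_v(a, "position", c(x, 0, 0))
  }
  expect_equal(mol_center(mol), c(1, 0, 0))
  c0 <- mol_center(mol)
  mol_translate(mol, c(1, -2, 3))
  expect_equal(mol_center(mol), c0 + c(1, -2, 3))
  # mass-weighted center differs when masses differ
  set_i(handle(mol, "atom", 2), "element", 8L)
  expect_gt(mass_center(mol)[1], 1)
  expect_error(mol_center(new_molecule("empty")), "empty")
})

test_that("length rule assigns orders from covalent-radius bands", {
  mk2 <- function(d, elem = 6L) {
    mol <- new_molecule("x")
    for (k in 1:2) { a <- create_object(mol, "atom"); set_i(a, "element", elem) }
    set_v(handle(mol, "atom", 1), "position", c(0, 0, 0))
    set_v(handle(mol, "atom", 2), "position", c(d, 0, 0))
    add_bond(mol, 1, 2, 0L)
    fixbond(mol)
    unname(bond_table(mol)[1, 3])
  }
  expect_equal(mk2(1.54), 1L)  # ethane C-C
  expect_equal(mk2(1.33), 2L)  # ethene C=C
  expect_equal(mk2(1.20), 3L)  # ethyne
})

test_that("benzene geometry with unset orders Kekulizes to alternating 1/2", {
  bz <- fx_benzene()
  set_col(bz, "bond", "order", "i", rep(0L, 12))
  fixbond(bz)
  bt <- bond_table(bz)
  ring <- which(bt[, 1] <= 6 & bt[, 2] <= 6)
  expect_equal(sort(bt[ring, 3]), c(1L, 1L, 1L, 2L, 2L, 2L))
  vs <- relmol:::.valence_sums(bt, bt[, 3], n_atoms(bz))
  expect_equal(vs[1:6], rep(4, 6))   # every carbon at valence 4
  # alternation: no two adjacent ring doubles
  for (b in ring) {
    if (bt[b, 3] == 2L) {
      others <- setdiff(ring, b)
      shared <- others[bt[others, 1] %in% bt[b, 1:2] | bt[others, 2] %in% bt[b, 1:2]]
      expect_true(all(bt[shared, 3] == 1L))
    }
  }
})

test_that("hard-rule templates fix carboxylate and nitro groups", {
  # carboxylate: C with two terminal oxygens at ambiguous lengths
  mol <- new_molecule("cbx")
  coords <- rbind(c(0, 0, 0), c(1.26, 0.3, 0), c(-0.6, 1.15, 0), c(-0.9, -1.1, 0))
  elems <- c(6L, 8L, 8L, 6L)
  for (k in 1:4) {
    a <- create_object(mol, "atom"); set_i(a, "element", elems[k])
    set_v(a, "position", coords[k, ])
  }
  add_bond(mol, 1, 2, 0L); add_bond(mol, 1, 3, 0L); add_bond(mol, 1, 4, 0L)
  fixbond(mol)
  bt <- bond_table(mol)
  expect_setequal(bt[1:2, 3], c(2L, 1L))
  expect_equal(unname(bt[1, 3]), 2L)  # lowest-index terminal O takes the double bond
})

test_that("valence contradictions are reported with offending atoms", {
  mol <- new_molecule("bad")
  for (k in 1:3) { a <- create_object(mol, "atom"); set_i(a, "element", 1L) }
  set_v(handle(mol, "atom", 1), "position", c(0, 0, 0))
  set_v(handle(mol, "atom", 2), "position", c(0.7, 0, 0))
  set_v(handle(mol, "atom", 3), "position", c(-0.7, 0, 0))
  add_bond(mol, 1, 2, 1L); add_bond(mol, 1, 3, 1L)
  expect_error(fixbond(mol), "valence contradiction")
})

test_that("addHs completes standard valences with idealized geometry", {
  o <- new_molecule("o")
  a <- create_object(o, "atom"); set_i(a, "element", 8L)
  set_v(a, "position", c(0, 0, 0)); set_s(a, "name", "O")
  addHs(o)
  expect_equal(n_atoms(o), 3L)
  expect_equal(sum(col_of(o, "atom", "element", "i") == 1L), 2L)
  # bare carbon: 4 H at 109.47 degrees pairwise
  c0 <- new_molecule("c")
  a <- create_object(c0, "atom"); set_i(a, "element", 6L)
  set_v(a, "position", c(0, 0, 0))
  addHs(c0)
  expect_equal(n_atoms(c0), 5L)
  p <- positions(c0)
  hs <- 2:5
  for (i in 2:4) for (j in (i + 1):5) {
    u <- p[i, ] / sqrt(sum(p[i, ]^2)); v <- p[j, ] / sqrt(sum(p[j, ]^2))
    ang <- acos(sum(u * v)) * 180 / pi
    expect_lt(abs(ang - 109.4712), 0.1)
  }
  expect_lt(abs(sqrt(sum(p[2, ]^2)) - 1.09), 1e-6)
  # benzene ring carbons get one in-plane H each
  bz <- fx_benzene()
  for (id in 12:7) delete_object(handle(bz, "atom", id))
  addHs(bz)
  expect_equal(n_atoms(bz), 12L)
  p <- positions(bz)
  expect_lt(max(abs(p[7:12, 3])), 1e-8)   # in-plane (z = 0)
  # heavy-atom formula unchanged; H count equals the valence deficit
  expect_equal(sum(col_of(bz, "atom", "element", "i") == 6L), 6L)
  expect_error({
    bad <- new_molecule("bad")
    a <- create_object(bad, "atom"); set_i(a, "element", 8L)
    set_v(a, "position", c(0, 0, 0))
    for (k in 1:3) {
      h <- create_object(bad, "atom"); set_i(h, "element", 1L)
      set_v(h, "position", rnorm(3))
      add_bond(bad, 1, h$id, 1L)
    }
    addHs(bad)
  }, "exceeds")
})

test_that("addHs hydrogen count equals the summed valence deficit", {
  set.seed(11)
  for (smi in c("CCO", "CC(=O)O", "c1ccccc1", "CNC", "CS")) {
    mol <- read_smiles(smi)
    deficit <- sum(col_of(mol, "atom", "nh", "i"))
    heavy0 <- sum(col_of(mol, "atom", "element", "i") > 1L)
    addHs(mol)
    elem <- col_of(mol, "atom", "element", "i")
    expect_equal(sum(elem > 1L), heavy0)
    expect_equal(sum(elem == 1L), deficit)
  }
})
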