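test_that("frcmod parsing stores symmetric keys and multi-term torsions", {
  ff <- read_frc(text = c("title", "BOND", "CT-HC  340.0  1.090"))
  expect_equal(ff_bond(ff, "CT", "HC")[["k"]], 340.0)
  expect_equal(ff_bond(ff, "HC", "CT")[["r0"]], 1.090)
  # negative periodicity continuation: two Fourier terms under one key
  ff2 <- read_frc(text = c("t", "DIHE",
                           "CT-CT-CT-CT   1    0.20    180.0   -2.",
                           "CT-CT-CT-CT   1    0.25      0.0    3."))
  terms <- ff_torsion(ff2, "CT", "CT", "CT", "CT")
  expect_length(terms, 2L)
  expect_equal(terms[[1]]$pn, 2)
  expect_equal(terms[[2]]$pn, 3)
  # empty NONBON: lookups error cleanly
  ff3 <- read_frc(text = c("t", "NONBON"))
  expect_error(ff_vdw(ff3, "CT"), "missing NONBON")
  expect_error(ff_bond(ff3, "QQ", "ZZ"), "missing BOND.*QQ.*ZZ")
  # frcmod overlay replaces matching keys
  ov <- read_frc(text = c("t", "BOND", "CT-HC  999.0  1.200"),
                 base = read_frc(text = fx_tiny_frc()))
  expect_equal(ff_bond(ov, "CT", "HC")[["k"]], 999.0)
  expect_equal(ff_bond(ov, "OW", "HW")[["k"]], 553.0)
  expect_error(read_frc(text = c("t", "BOND", "CT-HC  abc  1.0")), "BOND at line")
})

test_that("sequential parm.dat layout parses the same tables", {
  parm <- c("toy parm set",
            "CT 12.01", "HC 1.008", "",
            "CT",
            "CT-HC  340.0  1.090", "",
            "HC-CT-HC  35.0  109.5", "",
            "X -CT-CT-X    9   1.40    0.0    3.", "",
            "X -X -CT-HC  1.1  180.0  2.", "",
            "", "",
            "MOD4      RE",
            "  CT  1.9080  0.1094", "  HC  1.4870  0.0157", "",
            "END")
  ff <- read_frc(text = parm)
  expect_equal(ff_mass(ff, "CT"), 12.01)
  expect_equal(ff_bond(ff, "HC", "CT")[["k"]], 340)
  expect_equal(ff_angle(ff, "HC", "CT", "HC")[["theta0"]], 109.5)
  expect_equal(ff_torsion(ff, "HC", "CT", "CT", "HC")[[1]]$idivf, 9)
  expect_equal(ff_vdw(ff, "HC")[["eps"]], 0.0157)
})

test_that("term enumeration matches brute-force counts and is idempotent", {
  ch <- new_molecule("chain")
  for (k in 1:4) {
    a <- create_object(ch, "atom"); set_i(a, "element", 6L)
    set_v(a, "position", c(1.5 * k, k %% 2, 0))
  }
  add_bond(ch, 1, 2); add_bond(ch, 2, 3); add_bond(ch, 3, 4)
  enumerate_terms(ch)
  expect_equal(mol_count(ch, "angl"), 2L)
  expect_equal(mol_count(ch, "tors"), 1L)
  mth <- fx_methane()
  enumerate_terms(mth)
  expect_equal(mol_count(mth, "angl"), 6L)   # choose(4, 2)
  expect_equal(mol_count(mth, "tors"), 0L)
  enumerate_terms(mth)
  expect_equal(mol_count(mth, "angl"), 6L)   # re-run adds nothing
  # benzene: 6 ring + 6 C-H bonds -> 6*3 angles, ring torsions unique
  bz <- fx_benzene()
  enumerate_terms(bz)
  expect_equal(mol_count(bz, "angl"), 18L)
  expect_equal(mol_count(bz, "tors"), 24L)
  expect_equal(mol_count(bz, "oops"), 6L)
})

test_that("bonded energies reproduce hand-evaluated closed forms", {
  ffh <- read_frc(text = c("t", "BOND", "ZZ-ZZ 100.0 1.0",
                           "ANGLE", "ZZ-ZZ-ZZ  10.0  90.0",
                           "DIHE", "ZZ-ZZ-ZZ-ZZ  1  1.0  0.0  1."))
  mk <- function(coords) {
    mol <- new_molecule("m")
    for (k in seq_len(nrow(coords))) {
      a <- create_object(mol, "atom")
      set_i(a, "element", 6L); set_s(a, "type", "ZZ")
      set_v(a, "position", coords[k, ])
    }
    for (k in seq_len(nrow(coords) - 1)) add_bond(mol, k, k + 1)
    enumerate_terms(mol)
    mol
  }
  # one bond k=100, r0=1.0, r=1.1 -> 1.0 kcal/mol
  expect_equal(eval_bond(mk(rbind(c(0, 0, 0), c(1.1, 0, 0))), ffh), 1.0)
  # angle at theta0 -> 0
  m3 <- mk(rbind(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0)))
  expect_equal(eval_angl(m3, ffh), 0)
  m3b <- mk(rbind(c(1, 0, 0), c(0, 0, 0), c(-1, 1e-8, 0)))
  expect_equal(eval_angl(m3b, ffh), 10 * (pi / 2)^2, tolerance = 1e-6)
  # torsion V/2=1, n=1, gamma=0 at phi=0 -> 2.0
  m4 <- mk(rbind(c(1, 1, 0), c(0, 0, 0), c(1, 0, 0), c(0.0, 1, 0) + c(1, 0, 0) * 1))
  expect_equal(eval_tors(m4, ffh), 2.0, tolerance = 1e-9)
  # multi-term torsion equals the sum of its Fourier terms
  ffm <- read_frc(text = c("t", "DIHE",
                           "ZZ-ZZ-ZZ-ZZ  1  0.7  30.0  -1.",
                           "ZZ-ZZ-ZZ-ZZ  1  1.3  180.0  2."))
  ff1 <- read_frc(text = c("t", "DIHE", "ZZ-ZZ-ZZ-ZZ  1  0.7  30.0  1."))
  ff2 <- read_frc(text = c("t", "DIHE", "ZZ-ZZ-ZZ-ZZ  1  1.3  180.0  2."))
  m5 <- mk(rbind(c(1, 1, 0.3), c(0, 0, 0), c(1.2, 0, 0), c(1.7, 0.8, -0.4)))
  expect_equal(eval_tors(m5, ffm), eval_tors(m5, ff1) + eval_tors(m5, ff2),
               tolerance = 1e-12)
  expect_error(eval_bond(mk(rbind(c(0, 0, 0), c(1, 0, 0))),
                         read_frc(text = c("t", "BOND", "AA-AA 1.0 1.0"))),
               "missing BOND.*ZZ")
})

test_that("direct nonbonded sum matches constants, exclusions and the LJ minimum", {
  ffq <- read_frc(text = c("t", "NONBON", "QQ 0.0 0.0", "LJ 1.5 0.25"))
  two <- function(d, type, q) {
    mol <- new_molecule("2")
    for (k in 1:2) {
      a <- create_object(mol, "atom"); set_i(a, "element", 6L)
      set_s(a, "type", type); set_d(a, "pchg", q)
    }
    set_v(handle(mol, "atom", 1), "position", c(0, 0, 0))
    set_v(handle(mol, "atom", 2), "position", c(d, 0, 0))
    mol
  }
  # two unit charges 1 A apart -> the conversion constant itself
  e <- nonbond_direct(two(1, "QQ", 1), ffq)
  expect_equal(e[["elec"]], relmol::INVCHG2)
  expect_equal(e[["vdw"]], 0)
  # LJ at the pair minimum r = Rmin -> -eps
  e2 <- nonbond_direct(two(3.0, "LJ", 0), ffq)
  expect_equal(e2[["vdw"]], -0.25, tolerance = 1e-12)
  # a 1-2 bonded pair contributes nothing
  b2 <- two(1, "QQ", 1); add_bond(b2, 1, 2)
  e3 <- nonbond_direct(b2, ffq)
  expect_equal(e3[["elec"]], 0)
})

test_that("direct sum equals the O(n^2) brute-force oracle within 1e-9", {
  ff <- read_frc(text = fx_tiny_frc())
  set.seed(31)
  # random bonded clusters of water-type atoms
  for (trial in 1:3) {
    mol <- new_molecule("nb")
    n <- sample(30:60, 1)
    for (k in seq_len(n)) {
      a <- create_object(mol, "atom")
      set_i(a, "element", sample(c(6L, 8L), 1))
      set_s(a, "type", sample(c("CT", "OW", "O"), 1))
      set_d(a, "pchg", round(runif(1, -0.6, 0.6), 3))
      set_v(a, "position", runif(3, 0, 12))
      if (k > 1 && runif(1) < 0.6) add_bond(mol, sample(k - 1, 1), k)
    }
    got <- nonbond_direct(mol, ff)
    ref <- oracle_nonbond(mol, ff)
    expect_lt(abs(got[["elec"]] - ref[["elec"]]), 1e-9)
    expect_lt(abs(got[["vdw"]] - ref[["vdw"]]), 1e-9)
    # and under minimum-image PBC with a cutoff
    box <- c(20, 20, 20)
    gotp <- nonbond_direct(mol, ff, cutoff = 9, box = box)
    refp <- oracle_nonbond(mol, ff, cutoff = 9, box = box)
    expect_lt(abs(gotp[["elec"]] - refp[["elec"]]), 1e-9)
    expect_lt(abs(gotp[["vdw"]] - refp[["vdw"]]), 1e-9)
  }
  expect_error(nonbond_direct(fx_water(), ff, cutoff = 12, box = c(20, 20, 20)),
               "half the shortest box edge")
})

test_that("GB energy reproduces its closed forms and bounds", {
  # two atoms, q = +1 e, r = 0, alpha = 1 A: f_GB = 1, E = -INVCHG2 (1 - 1/78.5)
  mol <- new_molecule("gb")
  for (k in 1:2) {
    a <- create_object(mol, "atom"); set_i(a, "element", 6L)
    set_d(a, "pchg", 1); set_d(a, "born", 1); set_v(a, "position", c(0, 0, 0))
  }
  e <- nonbond_egb(mol)
  expect_equal(e, -relmol::INVCHG2 * (1 - 1 / 78.5), tolerance = 1e-12)
  # large separation: pair term approaches the screened Coulomb limit
  set_v(handle(mol, "atom", 2), "position", c(40, 0, 0))
  e_far <- nonbond_egb(mol)
  expect_equal(e_far, -relmol::INVCHG2 * (1 - 1 / 78.5) / 40, tolerance = 1e-6)
  # f_GB bounds: r <= f_GB <= sqrt(r^2 + alpha_ij^2), checked directly
  set.seed(8)
  for (k in 1:200) {
    r <- runif(1, 0, 10); ai <- runif(1, 0.5, 3); aj <- runif(1, 0.5, 3)
    ab <- ai * aj
    f <- sqrt(r^2 + ab * exp(-r^2 / (2 * ab)))
    expect_gte(f, r)
    expect_lte(f, sqrt(r^2 + ab) + 1e-12)
  }
  expect_error(nonbond_egb({
    m <- new_molecule("x")
    a <- create_object(m, "atom"); set_v(a, "position", c(0, 0, 0))
    b <- create_object(m, "atom"); set_v(b, "position", c(1, 0, 0))
    m
  }), "missing partial charge")
})

test_that("GB energy is invariant under relabeling and rigid motion", {
  set.seed(21)
  mol <- new_molecule("g")
  n <- 12
  for (k in seq_len(n)) {
    a <- create_object(mol, "atom"); set_i(a, "element", sample(c(6L, 7L, 8L), 1))
    set_d(a, "pchg", runif(1, -0.5, 0.5)); set_d(a, "born", runif(1, 1, 2))
    set_v(a, "position", runif(3, -5, 5))
  }
  e0 <- nonbond_egb(mol)
  mol_rotate(mol, c(1, 2, 3), 77, origin = c(1, 1, 1))
  mol_translate(mol, c(-4, 2, 9))
  expect_equal(nonbond_egb(mol), e0, tolerance = 1e-9)
  # relabeling: reversed atom order gives the same sum
  rev_mol <- new_molecule("gr")
  pos <- positions(mol)
  q <- col_of(mol, "atom", "pchg", "d"); brn <- col_of(mol, "atom", "born", "d")
  for (k in rev(seq_len(n))) {
    a <- create_object(rev_mol, "atom")
    set_d(a, "pchg", q[k]); set_d(a, "born", brn[k])
    set_v(a, "position", pos[k, ])
  }
  expect_equal(nonbond_egb(rev_mol), e0, tolerance = 1e-9)
  # the standard-variant switch changes the screening denominator only
  expect_false(isTRUE(all.equal(nonbond_egb(mol, variant = "standard"), e0)))
})

test_that("the conversion constant is consistent with first principles", {
  expect_equal(relmol::INVCHG2, 18.2223^2)
  # CODATA recomputation lands within ~0.015 of the AMBER convention value
  expect_lt(abs(coulomb_constant() - relmol::INVCHG2), 0.02)
})

test_that("energy_report totals its parts", {
  w <- fx_water()
  ff <- read_frc(text = fx_tiny_frc())
  enumerate_terms(w)
  rep <- energy_report(w, ff)
  expect_equal(rep$total,
               rep$bond + rep$angle + rep$torsion + rep$improper +
                 rep$elec_direct + rep$vdw + rep$egb,
               tolerance = 1e-9)
  df <- as.data.frame(rep)
  expect_true("total" %in% df$term)
})
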