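small_tmpl <- function() water_box_template(nside = 3L, spacing = 3.1)

random_solute <- function(seed, n = 6) {
  set.seed(seed)
  mol <- new_molecule(paste0("sol", seed))
  r <- create_object(mol, "resd"); set_s(r, "name", "LIG"); set_i(r, "seq", 1L)
  for (k in seq_len(n)) {
    a <- create_object(mol, "atom")
    set_i(a, "element", sample(c(6L, 7L, 8L), 1))
    set_s(a, "name", paste0("X", k)); set_s(a, "type", "CT")
    set_d(a, "pchg", round(runif(1, -0.3, 0.3), 3))
    set_v(a, "position", runif(3, -3, 3))
    relate(r, a)
  }
  mol
}

test_that("shell retention equals the brute-force per-solvent distance filter", {
  tmpl <- small_tmpl()
  td <- relmol:::.template_data(tmpl)
  for (seed in 1:12) {
    mol <- random_solute(seed)
    closeness <- runif(1, 0.7, 1.2)
    extent <- runif(1, 4, 8)
    solute_pos <- positions(mol)
    solute_elem <- col_of(mol, "atom", "element", "i")
    n0 <- n_residues(mol)
    solvate_shell(mol, tmpl, closeness, extent)
    kept_pkg <- n_residues(mol) - n0
    # oracle: re-tile and filter every solvent copy with plain loops
    bb <- list(lo = apply(solute_pos, 2, min) - extent,
               hi = apply(solute_pos, 2, max) + extent)
    shifts <- relmol:::.tile_shifts(bb$lo, bb$hi, td$solvlen)
    kept_oracle <- 0L
    for (s in seq_len(nrow(shifts))) {
      spos <- sweep(td$pos, 2, shifts[s, ], `+`)
      keep <- oracle_shell_keep(solute_pos, solute_elem, spos, td$elem,
                                td$res_of, closeness, extent)
      kept_oracle <- kept_oracle + sum(keep)
    }
    expect_equal(kept_pkg, kept_oracle, info = paste("seed", seed))
  }
})

test_that("retained solvents never clash and lie within the shell band", {
  tmpl <- small_tmpl()
  for (seed in 13:18) {
    mol <- random_solute(seed)
    nsol <- n_atoms(mol)
    closeness <- 1.0; extent <- 6
    solvate_shell(mol, tmpl, closeness, extent)
    pos <- positions(mol)
    elem <- col_of(mol, "atom", "element", "i")
    res_of <- relmol:::.residue_of_atoms(mol)
    solv_res <- which(col_or(mol, "resd", "solvent", "i", 0L) == 1L)
    for (r in solv_res) {
      ids <- which(res_of == r)
      dmin <- Inf
      for (a in ids) {
        d <- sqrt(rowSums((pos[seq_len(nsol), , drop = FALSE] -
                             matrix(pos[a, ], nsol, 3, byrow = TRUE))^2))
        cut <- closeness * (element_vdw(elem[a]) + element_vdw(elem[seq_len(nsol)]))
        expect_true(all(d >= cut))
        dmin <- min(dmin, min(d))
      }
      expect_lte(dmin, extent)
    }
  }
})

test_that("an unreachable shell band retains zero solvents without error", {
  mol <- random_solute(99, n = 1)
  n0 <- n_residues(mol)
  added <- solvate_shell(mol, small_tmpl(), closeness = 1.0, extent = 0.5)
  expect_equal(added, 0L)
  expect_equal(n_residues(mol), n0)
})

test_that("octahedral solvation never places more solvents than the box", {
  tmpl <- small_tmpl()
  for (seed in 21:32) {
    m_box <- random_solute(seed); m_oct <- random_solute(seed)
    buffer <- runif(1, 6, 12)
    nb <- solvate_box(m_box, tmpl, buffer)
    no <- solvate_oct(m_oct, tmpl, buffer)
    expect_lte(no, nb)
    expect_gt(nb, 0)
    expect_equal(m_box$props$box$shape, "box")
    expect_equal(m_oct$props$box$shape, "oct")
  }
})

test_that("box mode keeps solvent centroids inside the stated region", {
  tmpl <- small_tmpl()
  mol <- new_molecule("pt")
  a <- create_object(mol, "atom"); set_i(a, "element", 6L); set_s(a, "type", "CT")
  set_v(a, "position", c(0, 0, 0))
  r <- create_object(mol, "resd"); relate(r, a)
  solvate_box(mol, tmpl, buffer = 10)
  pos <- positions(mol)
  res_of <- relmol:::.residue_of_atoms(mol)
  solv <- which(col_or(mol, "resd", "solvent", "i", 0L) == 1L)
  for (rr in solv) {
    cent <- colMeans(pos[res_of == rr, , drop = FALSE])
    expect_true(all(cent >= -10 - 1e-9) && all(cent <= 10 + 1e-9))
  }
  # cap: all retained centroids within the cap radius of the cap center
  mol2 <- new_molecule("pt2")
  a <- create_object(mol2, "atom"); set_i(a, "element", 6L)
  set_v(a, "position", c(0, 0, 0))
  r <- create_object(mol2, "resd"); relate(r, a)
  ctr <- c(7, 0, 0)
  solvate_cap(mol2, tmpl, ctr, radius = 5)
  pos2 <- positions(mol2)
  res_of2 <- relmol:::.residue_of_atoms(mol2)
  for (rr in which(col_or(mol2, "resd", "solvent", "i", 0L) == 1L)) {
    cent <- colMeans(pos2[res_of2 == rr, , drop = FALSE])
    expect_lte(sqrt(sum((cent - ctr)^2)), 5 + 1e-9)
  }
})

test_that("tiling is deterministic and every shell solvent also appears in the box", {
  tmpl <- small_tmpl()
  m1 <- random_solute(41); m2 <- random_solute(41)
  solvate_shell(m1, tmpl, 1.0, 6); solvate_shell(m2, tmpl, 1.0, 6)
  expect_equal(positions(m1), positions(m2))
  # shell subset of box at buffer = extent, equal closeness
  m_shell <- random_solute(42); m_box <- random_solute(42)
  solvate_shell(m_shell, tmpl, 1.0, 6)
  solvate_box(m_box, tmpl, buffer = 6)
  key <- function(m) {
    res_of <- relmol:::.residue_of_atoms(m)
    solv <- which(col_or(m, "resd", "solvent", "i", 0L) == 1L)
    pos <- positions(m)
    sort(vapply(solv, function(r)
      paste(round(colMeans(pos[res_of == r, , drop = FALSE]), 6), collapse = ","),
      character(1)))
  }
  expect_true(all(key(m_shell) %in% key(m_box)))
})

test_that("ion placement neutralizes and respects the distance floor", {
  sol <- random_solute(77)
  set_col(sol, "atom", "pchg", "d", rep(-2 / n_atoms(sol), n_atoms(sol)))
  placed <- addions(sol, fx_ion("Na+"), "auto")
  expect_equal(placed, 2L)
  q <- col_of(sol, "atom", "pchg", "d")
  expect_lt(abs(sum(q)), 1e-9)
  pos <- positions(sol)
  ion_rows <- which(col_of(sol, "atom", "element", "i") == 11L)
  for (i in ion_rows) {
    d <- sqrt(rowSums((pos[-i, , drop = FALSE] -
                         matrix(pos[i, ], nrow(pos) - 1, 3, byrow = TRUE))^2))
    expect_gte(min(d), 3.0)
  }
  # zero net charge is a no-op with a notice
  neutral <- random_solute(78)
  set_col(neutral, "atom", "pchg", "d", rep(0, n_atoms(neutral)))
  expect_message(n0 <- addions(neutral, fx_ion("Cl-"), "auto"), "zero")
  expect_equal(n0, 0L)
  # explicit count places exactly that many
  m3 <- random_solute(79)
  expect_equal(addions(m3, fx_ion("Cl-"), 3), 3L)
  expect_equal(sum(col_of(m3, "atom", "element", "i") == 17L), 3L)
})
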