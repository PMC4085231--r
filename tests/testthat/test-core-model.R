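test_that("name hashing follows the base-40 character rules", {
  expect_equal(encode_name("_"), 36)
  expect_equal(encode_name("a"), 0)
  expect_equal(encode_name("A"), 0)
  expect_equal(encode_name("ba"), 40)
  expect_equal(encode_name("atom"), 30972)
  expect_equal(encode_name("a!b"), encode_name("ab"))
  expect_equal(encode_name("9"), 9)
  expect_error(encode_name("!!"), "admissible")
  expect_error(encode_name("abcdefghijk"), "more than 10")
  # exactly ten admissible characters is allowed
  expect_silent(encode_name("abcdefghij"))
})

test_that("hashing matches a positional base-40 oracle and is injective away from leading zeros", {
  alphabet <- c("b", "d", "z", "Q", "_")   # pairwise-distinct digit values
  names <- alphabet
  for (len in 2:4)
    names <- c(names, apply(expand.grid(rep(list(alphabet), len)), 1, paste, collapse = ""))
  h <- encode_name(names)
  o <- vapply(names, oracle_encode, numeric(1), USE.NAMES = FALSE)
  expect_equal(h, o)
  expect_equal(anyDuplicated(h), 0L)
})

test_that("eight molecular-object type codes are registered and hash injectively", {
  codes <- type_codes()
  expect_true(all(c("atom", "bond", "resd", "angl", "tors", "oops",
                    "tor2", "ptor") %in% codes))
  h <- type_hashes()
  expect_equal(anyDuplicated(h[c("atom", "bond", "resd", "angl", "tors",
                                 "oops", "tor2", "ptor")]), 0L)
})

test_that("object creation extends tables with defaults and 1-based ids", {
  mol <- new_molecule("m")
  a1 <- create_object(mol, "atom")
  expect_equal(n_atoms(mol), 1L)
  set_i(a1, "element", 8L)
  a2 <- create_object(mol, "atom")
  expect_equal(a1$id, 1L)
  expect_equal(a2$id, 2L)
  # lazily created column backfills defaults; new object gets default too
  expect_equal(get_i(a2, "element"), 0L)
  b <- create_object(mol, "bond")
  expect_equal(n_bonds(mol), 1L)
  expect_length(related_ids(b, "atom"), 0L)
  expect_error(create_object(mol, "wxyz"), "unregistered")
})

test_that("properties round-trip across all five kinds with found-flag access", {
  mol <- new_molecule("m")
  a <- create_object(mol, "atom")
  set_i(a, "element", 8L); expect_identical(get_i(a, "element"), 8L)
  set_d(a, "pchg", -0.5); expect_identical(get_d(a, "pchg"), -0.5)
  set_s(a, "name", "O"); expect_identical(get_s(a, "name"), "O")
  set_v(a, "position", c(1, 2, 3))
  expect_equal(get_v(a, "position"), c(1, 2, 3))
  # flat storage of vector columns
  expect_equal(mol$cmp$atom$cols[[relmol:::.col_key("position")]]$data, c(1, 2, 3))
  set_a(a, "blob", list(x = 1)); expect_equal(get_a(a, "blob"), list(x = 1))
  miss <- try_prop(a, "missing", "s")
  expect_false(miss$found)
  expect_error(get_s(a, "missing"), "missing property")
  expect_error(get_d(a, "element"), "kind")
  # hash keys address the same column as names
  expect_identical(get_i(a, encode_name("element")), 8L)
})

test_that("relations are symmetric, ordered, and deduplicated", {
  mol <- new_molecule("m")
  a <- create_object(mol, "atom")
  b <- create_object(mol, "bond")
  r <- create_object(mol, "resd")
  relate(a, b); relate(a, b)
  expect_equal(related_ids(a, "bond"), 1L)
  expect_equal(related_ids(b, "atom"), 1L)
  relate(r, a)
  expect_equal(related_ids(r, "atom"), 1L)
  expect_equal(related_ids(a, "resd"), 1L)
  other <- new_molecule("x")
  a2 <- create_object(other, "atom")
  expect_error(relate(a, a2), "different molecules")
})

test_that("iteration is per-type with constant-time counts and random access", {
  mol <- new_molecule("m")
  for (k in 1:3) create_object(mol, "atom")
  for (k in 1:2) create_object(mol, "resd")
  atoms <- objects(mol, "atom")
  expect_length(atoms, 3L)
  expect_equal(vapply(atoms, `[[`, integer(1), "id"), 1:3)
  expect_equal(mol_count(mol, "resd"), 2L)
  expect_equal(atoms[[2]]$id, objects(mol, "atom")[[2]]$id)
  b <- add_bond(mol, 1, 2)
  expect_equal(related_ids(b, "atom"), c(1L, 2L))
})

test_that("deletion cascades to dependent objects and compacts ids", {
  mol <- new_molecule("m")
  a <- create_object(mol, "atom")
  delete_object(a)
  expect_equal(n_atoms(mol), 0L)
  # bonded pair: deleting one atom removes the bond
  mol <- new_molecule("m")
  for (k in 1:2) { x <- create_object(mol, "atom"); set_i(x, "element", 6L) }
  add_bond(mol, 1, 2)
  delete_object(handle(mol, "atom", 1))
  expect_equal(n_atoms(mol), 1L)
  expect_equal(n_bonds(mol), 0L)
  # A-B-C with an angle: deleting B removes both bonds and the angle
  mol <- new_molecule("m")
  for (k in 1:3) { x <- create_object(mol, "atom"); set_s(x, "name", LETTERS[k]) }
  add_bond(mol, 1, 2); add_bond(mol, 2, 3)
  ang <- create_object(mol, "angl")
  for (k in 1:3) relate(ang, handle(mol, "atom", k))
  delete_object(handle(mol, "atom", 2))
  expect_equal(n_atoms(mol), 2L)
  expect_equal(n_bonds(mol), 0L)
  expect_equal(mol_count(mol, "angl"), 0L)
  expect_equal(col_of(mol, "atom", "name", "s"), c("A", "C"))
  expect_error(handle(mol, "atom", 3), "stale|out-of-range")
})

test_that("random mutation sequences preserve referential integrity", {
  set.seed(42)
  for (trial in 1:10) {
    mol <- new_molecule("fuzz")
    for (step in 1:60) {
      op <- sample(3, 1)
      if (op == 1 || n_atoms(mol) < 2) {
        a <- create_object(mol, "atom")
        if (n_atoms(mol) > 1 && runif(1) < 0.7)
          add_bond(mol, sample(n_atoms(mol) - 1, 1), a$id)
      } else if (op == 2) {
        r <- create_object(mol, "resd")
        for (id in sample(n_atoms(mol), min(3, n_atoms(mol))))
          relate(r, handle(mol, "atom", id))
      } else if (n_atoms(mol) > 0) {
        delete_object(handle(mol, "atom", sample(n_atoms(mol), 1)))
      }
    }
    # every adjacency index is live, relations symmetric, columns full length
    for (key in names(mol$adj)) {
      parts <- strsplit(key, ".", fixed = TRUE)[[1]]
      expect_length(mol$adj[[key]], mol_count(mol, parts[1]))
      for (src in seq_along(mol$adj[[key]])) {
        tgt <- mol$adj[[key]][[src]]
        expect_true(all(tgt >= 1 & tgt <= mol_count(mol, parts[2])))
        back <- relmol:::.adj_key(parts[2], parts[1])
        for (t in tgt) expect_true(src %in% mol$adj[[back]][[t]])
      }
    }
    for (type in names(mol$cmp)) {
      for (col in mol$cmp[[type]]$cols) {
        expected <- mol$cmp[[type]]$n * max(1L, col$width)
        expect_length(col$data, expected)
      }
    }
  }
})

test_that("a ninth type code can be registered without disturbing iteration", {
  mol <- new_molecule("dna")
  for (k in 1:4) create_object(mol, "atom")
  for (k in 1:2) create_object(mol, "resd")
  before_atoms <- vapply(objects(mol, "atom"), `[[`, integer(1), "id")
  register_type("strd")
  expect_true("strd" %in% type_codes())
  s <- create_object(mol, "strd")
  relate(s, handle(mol, "resd", 1))
  relate(s, handle(mol, "resd", 2))
  expect_equal(related_ids(s, "resd"), c(1L, 2L))
  expect_equal(vapply(objects(mol, "atom"), `[[`, integer(1), "id"), before_atoms)
  expect_equal(n_residues(mol), 2L)
})

test_that("molecule database stores and retrieves by name", {
  db <- new_database()
  w <- new_molecule("wat")
  db_put(db, "wat", w)
  expect_identical(db_get_mol(db, "wat"), w)
  expect_error(db_get_mol(db, "missing"), "not found")
  w2 <- new_molecule("wat2")
  db_put(db, "wat", w2)
  expect_identical(db_get_mol(db, "wat"), w2)
  expect_error(db_put(db, "", w), "non-empty")
  expect_equal(db_size(db), 1L)
})
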