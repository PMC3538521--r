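test_that("SMILES parsing perceives aromaticity, components and hydrogens", {
  b <- parse_smiles("c1ccccc1")
  expect_equal(n_atoms(b), 6)
  expect_true(all(b$aromatic))
  expect_equal(sum(b$bond_aromatic), 6)
  expect_equal(b$nH, rep(1L, 6))

  # kekulized input is perceived aromatic too
  kek <- parse_smiles("C1=CC=CC=C1")
  expect_true(all(kek$aromatic))
  expect_equal(sum(kek$bond_aromatic), 6)
  # while cyclohexadiene-like and saturated rings are not
  expect_false(any(parse_smiles("C1CCCCC1")$aromatic))

  s <- parse_smiles("CC(=O)O.[Na+]")
  expect_equal(n_components(s), 2)
  expect_equal(sort(tabulate(components(s))), c(1, 4))
  expect_equal(s$charge[s$element == "Na"], 1L)

  nb <- parse_smiles("C1CC2CCC1C2")
  expect_equal(n_atoms(nb), 7)
  expect_equal(n_bonds(nb), 8)
  # cyclomatic number 2
  expect_equal(n_bonds(nb) - n_atoms(nb) + n_components(nb), 2)

  zw <- parse_smiles("C(C(=O)[O-])[NH3+]")
  expect_equal(sum(zw$charge), 0L)
  expect_equal(zw$nH[zw$element == "N"], 3L)
})

test_that("invalid SMILES are rejected with a typed error carrying the input", {
  for (bad in c("", "C(", "C1CC", "CX", "[Qq]", "C(C)(C)(C)(C)C")) {
    err <- tryCatch(parse_smiles(bad), error = function(e) e)
    expect_s3_class(err, "druglike_parse_error")
    expect_match(conditionMessage(err), "parse", fixed = TRUE)
  }
})

test_that("SMILES round trip preserves the structure key", {
  for (s in fixture_smiles()) {
    m <- parse_smiles(s)
    s2 <- write_smiles(m)
    m2 <- parse_smiles(s2)
    expect_equal(canonical_key(m2), canonical_key(m), label = paste("roundtrip", s))
  }
})

test_that("canonical keys are atom-order invariant and structure-sensitive", {
  expect_equal(canonical_key(parse_smiles("CCO")), canonical_key(parse_smiles("OCC")))
  expect_equal(canonical_key(parse_smiles("c1ccc(-c2ccccc2)cc1")),
               canonical_key(parse_smiles("c1ccc(cc1)-c1ccccc1")))
  expect_false(canonical_key(parse_smiles("CCO")) == canonical_key(parse_smiles("CCN")))
  expect_false(canonical_key(parse_smiles("CCC(C)O")) == canonical_key(parse_smiles("CCCCO")))
  set.seed(5)
  for (s in c("CC(=O)Nc1ccc(O)cc1", "C1C2CC3CC1CC(C2)C3")) {
    m <- parse_smiles(s)
    p <- permute_atoms(m, sample(n_atoms(m)))
    expect_equal(canonical_key(p), canonical_key(m))
  }
})

test_that("SMILES library files read records in order and log rejections", {
  f <- withr::local_tempfile(lines = c(
    "CCO ethanol", "C1CC oops", "c1ccccc1 benzene", "# comment", ""))
  lib <- read_library(f)
  expect_length(lib, 2)
  expect_equal(vapply(lib, function(m) m$name, character(1)), c("ethanol", "benzene"))
  rej <- attr(lib, "rejections")
  expect_equal(nrow(rej), 1)
  expect_equal(rej$record_index, 2)
  expect_equal(rej$input_text, "C1CC")

  empty <- withr::local_tempfile(lines = character())
  expect_length(read_library(empty), 0)
  expect_error(read_library("no/such/file.smi"), "no such file")
})

test_that("SDF V2000 records parse with names, charges and aromatic perception", {
  sdf <- c(
    "benzene", "", "",
    "  6  6  0  0  0  0  0  0  0  0999 V2000",
    rep("    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0", 6),
    "  1  2  2  0", "  2  3  1  0", "  3  4  2  0", "  4  5  1  0",
    "  5  6  2  0", "  6  1  1  0",
    "M  END", "$$$$",
    "acetate", "", "",
    "  4  3  0  0  0  0  0  0  0  0999 V2000",
    "    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "    0.0000    0.0000    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0",
    "    0.0000    0.0000    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0",
    "  1  2  1  0", "  2  3  2  0", "  2  4  1  0",
    "M  CHG  1   4  -1",
    "M  END", "$$$$")
  f <- withr::local_tempfile(lines = sdf)
  lib <- read_library(f, format = "sdf")
  expect_length(lib, 2)
  expect_equal(lib[[1]]$name, "benzene")
  expect_true(all(lib[[1]]$aromatic))
  expect_equal(lib[[2]]$charge[4], -1L)
  expect_equal(canonical_key(lib[[2]]), canonical_key(parse_smiles("CC(=O)[O-]")))
})

test_that("molecular weight uses average masses including hydrogens", {
  expect_equal(molecular_weight(parse_smiles("c1ccccc1")), 78.114, tolerance = 1e-6)
  expect_equal(molecular_weight(parse_smiles("O")), 18.015, tolerance = 1e-6)
})
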