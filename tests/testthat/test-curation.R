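test_that("curation strips salts, filters elements and deduplicates", {
  mols <- list(parse_smiles("CC(=O)O.[Na+]"), parse_smiles("C[Si](C)C"),
               parse_smiles("CCO"), parse_smiles("CCO"), parse_smiles("OCC"))
  cur <- curate_library(mols)
  rep <- attr(cur, "report")
  expect_equal(rep$fragments_stripped[rep$step == 2], 1)  # Na+ stripped
  expect_equal(rep$molecules_removed[rep$step == 3], 1)   # silicon
  expect_equal(rep$molecules_removed[rep$step == 6], 2)   # CCO == OCC
  expect_length(cur, 2)
  keys <- vapply(cur, canonical_key, character(1))
  expect_true(canonical_key(parse_smiles("CC(=O)O")) %in% keys)  # acid kept
  expect_true(canonical_key(parse_smiles("CCO")) %in% keys)
  # report balances
  expect_equal(length(mols) - sum(rep$molecules_removed), length(cur))
})

test_that("curation keeps the largest fragment and is idempotent", {
  mols <- list(parse_smiles("CCCCCCCC.CC"), parse_smiles("c1ccccc1.O"))
  cur <- curate_library(mols)
  expect_equal(vapply(cur, n_components, integer(1)), c(1L, 1L))
  expect_equal(n_atoms(cur[[1]]), 8)

  lib <- c(test_library("druglike", n = 30, seed = 21),
           list(parse_smiles("CC(=O)O.[Na+]"), parse_smiles("CCO")))
  once <- curate_library(lib)
  twice <- curate_library(once)
  expect_equal(vapply(twice, canonical_key, character(1)),
               vapply(once, canonical_key, character(1)))
  expect_equal(sum(attr(twice, "report")$molecules_removed), 0)
})

test_that("cross-library deduplication removes shared structures from A only", {
  A <- list(parse_smiles("CCO"), parse_smiles("c1ccccc1"))
  B <- list(parse_smiles("C1=CC=CC=C1"))  # benzene, kekulized encoding
  A2 <- cross_deduplicate(A, B)
  expect_length(A2, 1)
  expect_equal(canonical_key(A2[[1]]), canonical_key(parse_smiles("CCO")))
  expect_length(cross_deduplicate(A, list(parse_smiles("CCN"))), 2)
  expect_length(cross_deduplicate(A, c(A, B)), 0)
})

test_that("reactive-group flagging matches the named patterns", {
  r <- flag_reactive(parse_smiles("CC=O"))
  expect_true(r$reactive); expect_true("aldehyde" %in% r$groups)
  r <- flag_reactive(parse_smiles("CC(=O)Cl"))
  expect_true("acyl-halide" %in% r$groups)
  expect_false(flag_reactive(parse_smiles("c1ccccc1"))$reactive)
  expect_true("alkyl-halide" %in% flag_reactive(parse_smiles("CCBr"))$groups)
  expect_true("disulfide" %in% flag_reactive(parse_smiles("CSSC"))$groups)
  expect_true("peroxide" %in% flag_reactive(parse_smiles("CCOOC"))$groups)
  expect_true("quaternaryamine" %in% flag_reactive(parse_smiles("C[N+](C)(C)C"))$groups)
  expect_true("isocyanate" %in% flag_reactive(parse_smiles("CN=C=O"))$groups)
  expect_true("hydrazine-N-NH2" %in% flag_reactive(parse_smiles("CNN"))$groups)
  # amide, ester, aromatic chloride: none reactive
  for (s in c("CC(N)=O", "CC(=O)OC", "Clc1ccccc1"))
    expect_false(flag_reactive(parse_smiles(s))$reactive, label = s)
  expect_error(flag_reactive(parse_smiles("C"), patterns = list(1, 2)),
               "malformed")
})

test_that("a minority of the drug-like synthetic class is reactive", {
  lib <- test_library("druglike", n = 200, seed = 31)
  frac <- mean(vapply(lib, function(m) flag_reactive(m)$reactive, logical(1)))
  expect_gt(frac, 0)
  expect_lt(frac, 0.25)
})

test_that("MW cutoff is strict and monotone", {
  mols <- lapply(c("CCCCCC", "CCO", "c1ccccc1"), parse_smiles)
  mw <- vapply(mols, molecular_weight, numeric(1))
  kept <- apply_mw_cutoff(mols, mw[2])
  expect_length(kept, sum(mw < mw[2]))  # equality excluded
  expect_length(apply_mw_cutoff(list(), 600), 0)
  lib <- test_library("reagentlike", n = 60, seed = 41)
  k600 <- apply_mw_cutoff(lib, 600)
  k800 <- apply_mw_cutoff(lib, 800)
  expect_true(all(vapply(k600, write_smiles, character(1)) %in%
                  vapply(k800, write_smiles, character(1))))
})

test_that("MW-matched subsets track the reference distribution deterministically", {
  cand <- test_library("reagentlike", n = 400, seed = 51)
  # reference concentrated in a narrow window
  ref <- generate_library(library_spec("reagentlike", n = 150, rng_seed = 52,
                                       mw_window = c(250, 300)))
  sub <- build_mw_matched_subset(cand, ref, mw_match_spec(bin_width = 20, rng_seed = 3))
  mw_sub <- vapply(sub, molecular_weight, numeric(1))
  expect_gt(length(sub), 10)
  expect_gte(mean(mw_sub >= 240 & mw_sub <= 310), 0.9)

  # candidates == reference reproduces the whole set (KS ~ 0)
  sub2 <- build_mw_matched_subset(cand, cand, mw_match_spec(bin_width = 20, rng_seed = 3))
  expect_gt(length(sub2), 0.95 * length(cand))

  # determinism under the spec seed
  s1 <- build_mw_matched_subset(cand, ref, mw_match_spec(20, rng_seed = 9))
  s2 <- build_mw_matched_subset(cand, ref, mw_match_spec(20, rng_seed = 9))
  expect_identical(vapply(s1, write_smiles, character(1)),
                   vapply(s2, write_smiles, character(1)))
  expect_error(build_mw_matched_subset(cand, list()), "empty")
})
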