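test_that("composition, hydrogen-bond and rotatable counts match hand values", {
  b <- compute_descriptors(parse_smiles("c1ccccc1"),
                           which = c("MW", "N_C", "N_Atom", "N_Bonds"))
  expect_equal(unname(b["N_C"]), 6)
  expect_equal(unname(b["N_Atom"]), 6)
  expect_equal(unname(b["N_Bonds"]), 6)
  expect_equal(unname(b["MW"]), 78.114, tolerance = 1e-6)

  gz <- count_composition(parse_smiles("C(C(=O)[O-])[NH3+]"))
  expect_equal(unname(gz[c("N_positive", "N_negative")]), c(1, 1))
  expect_equal(unname(count_composition(parse_smiles("C(Cl)(Cl)Cl"))["N_Halogen"]), 3)

  eth <- count_hbonds(parse_smiles("CCO"))
  expect_equal(unname(eth[c("N_HBD", "N_HBA", "N_HBDL", "N_HBAL")]), c(1, 1, 1, 1))
  am <- count_hbonds(parse_smiles("CC(N)=O"))
  expect_equal(unname(am[c("N_HBAL", "N_HBDL")]), c(2, 2))
  expect_equal(unname(count_hbonds(parse_smiles("c1ccccc1"))), c(0, 0, 0, 0))

  expect_equal(unname(count_rotatable(parse_smiles("CCO"))), 0)
  expect_equal(unname(count_rotatable(parse_smiles("CCCC"))), 1)
  expect_equal(unname(count_rotatable(parse_smiles("c1ccccc1"))), 0)
  # amide C-N exclusion
  expect_equal(unname(count_rotatable(parse_smiles("CC(=O)NC"))), 0)
})

test_that("ring descriptors match the hand-derived polycyclic cases", {
  nb <- ring_descriptors(parse_smiles("C1CC2CCC1C2"))
  expect_equal(unname(nb[c("N_Rings", "N_R5", "N_Bridge", "N_BHA", "N_Spiro")]),
               c(2, 2, 8, 2, 0))
  dec <- ring_descriptors(parse_smiles("C1CCC2CCCCC2C1"))
  expect_equal(unname(dec[c("N_Bridge", "N_BHA", "N_RA", "N_Rings")]), c(0, 0, 1, 2))
  sp <- ring_descriptors(parse_smiles("C1CCC2(C1)CCCC2"))
  expect_equal(unname(sp[c("N_Spiro", "N_Bridge")]), c(1, 0))
  benz <- ring_descriptors(parse_smiles("c1ccccc1"))
  expect_equal(unname(benz[c("N_AR", "N_aromatic", "N_Ringb", "N_R6")]), c(1, 6, 6, 1))
})

test_that("chain and stereo descriptors follow their graph definitions", {
  tol <- chain_and_stereo(parse_smiles("Cc1ccccc1"))
  expect_equal(unname(tol["N_ChainA"]), 1)
  expect_equal(unname(tol["N_Chains"]), 1 + 8)  # hydrogens counted
  expect_equal(unname(chain_and_stereo(parse_smiles("FC(Cl)Br"))["N_Stereo"]), 1)
  expect_equal(unname(chain_and_stereo(parse_smiles("CC(C)C"))["N_Stereo"]), 0)
  expect_equal(unname(chain_and_stereo(parse_smiles("CC=CC"))["N_StereoB"]), 1)
  expect_equal(unname(chain_and_stereo(parse_smiles("CC=C"))["N_StereoB"]), 0)
  expect_equal(unname(chain_and_stereo(parse_smiles("CC=C(C)C"))["N_StereoB"]), 0)
})

test_that("subgraph counts equal exhaustive enumeration on small fixtures", {
  expect_equal(unname(subgraph_counts(parse_smiles("c1ccccc1"))),
               c(6, 6, 6, 6, 0, 0))
  expect_equal(unname(subgraph_counts(parse_smiles("C1CC1"))["SC3CH"]), 1)
  for (m in fixture_mols()) {
    if (n_atoms(m) > 12) next
    got <- subgraph_counts(m)
    expect_equal(unname(got[c("SC2", "SC3P", "SC3C", "SC3CH")]),
                 unname(enumerate_subgraph_counts(m)),
                 label = paste("subgraphs of", write_smiles(m)))
  }
})

test_that("logP is additive with sensible group effects", {
  tab <- crippen_table()
  ch4 <- compute_logp(parse_smiles("C"))
  expect_equal(as.numeric(ch4),
               tab$contribution[tab$type == "C.sp3"] +
                 4 * tab$contribution[tab$type == "H.C"], tolerance = 1e-12)
  expect_gt(compute_logp(parse_smiles("CCCCCC")), compute_logp(parse_smiles("CC")))
  expect_lt(compute_logp(parse_smiles("CCCCCCO")), compute_logp(parse_smiles("CCCCCC")))
})

test_that("topological PSA reflects polar fragments", {
  expect_equal(unname(compute_tpsa(parse_smiles("c1ccccc1"))), 0)
  expect_equal(unname(compute_tpsa(parse_smiles("CCO"))), 20.23)
  expect_gt(compute_tpsa(parse_smiles("CCO")), compute_tpsa(parse_smiles("CCOCC")))
  base <- compute_tpsa(parse_smiles("CCCCCC"))
  expect_gt(compute_tpsa(parse_smiles("CCCCCCO")), base)
})

test_that("logD and logS surrogates respond to ionization and size", {
  hexane <- parse_smiles("CCCCCC")
  dl <- compute_logd_logs(hexane)
  expect_equal(dl[["logD7.4"]], compute_logp(hexane)[["AlogP"]])  # no ionizable group
  asp <- parse_smiles("CC(=O)Oc1ccccc1C(=O)O")
  expect_lt(compute_logd_logs(asp)[["logD7.4"]], compute_logp(asp)[["AlogP"]])
  amine <- parse_smiles("CCCCCCN")
  expect_lt(compute_logd_logs(amine)[["logD7.4"]], compute_logp(amine)[["AlogP"]])
  # logS falls with MW at fixed other terms (c2 < 0 in the shipped table)
  co <- logs_coefficients()
  expect_lt(co$coefficient[co$term == "MW"], 0)
  p1 <- c(AlogP = 2, MW = 300, N_rot = 3, N_aromatic = 6)
  p2 <- p1; p2["MW"] <- 400
  expect_lt(compute_logd_logs(hexane, p2)[["logS"]],
            compute_logd_logs(hexane, p1)[["logS"]])
})

test_that("fractional surface descriptors partition the molecular surface", {
  for (s in c("CCO", "c1ccccc1", "CC(=O)Nc1ccc(O)cc1", "C(C(=O)[O-])[NH3+]")) {
    m <- parse_smiles(s)
    ann <- atom_annotations(m)
    sd <- surface_descriptors(m, ann)
    fasa0 <- 1 - sd[["FASA+"]] - sd[["FASA-"]]
    expect_gte(fasa0, -1e-9)
    expect_equal(sd[["FASA_H"]] + sd[["FASA_P"]], 1, tolerance = 1e-9)
    expect_equal(sd[["FVSA_H"]] + sd[["FVSA_P"]], 1, tolerance = 1e-9)
    expect_true(all(sd[-1] >= -1e-12 & sd[-1] <= 1 + 1e-12))
    expect_gt(sd[["MSA"]], 0)
  }
  expect_gt(surface_descriptors(parse_smiles("CCO"))[["FASA-"]],
            surface_descriptors(parse_smiles("CCCCCC"))[["FASA-"]])
})

test_that("ratio descriptors flag zero denominators instead of yielding NaN", {
  cy <- ratio_descriptors(parse_smiles("C1CCCCC1"))
  expect_equal(cy[["C3P"]], 1)
  expect_equal(cy[["UNC_C3"]], 0)
  expect_false("UNC_C3" %in% attr(cy, "flags"))
  bz <- ratio_descriptors(parse_smiles("c1ccccc1"))
  expect_equal(bz[["C3P"]], 0)
  expect_equal(bz[["UNC_C3"]], 0)
  expect_true("UNC_C3" %in% attr(bz, "flags"))
  sty <- ratio_descriptors(parse_smiles("C=Cc1ccccc1"))
  expect_true("UNC_C3" %in% attr(sty, "flags"))
})

test_that("the full vector has the 60 canonical names and is order-invariant", {
  dv <- compute_descriptors(parse_smiles("CC(=O)Nc1ccc(O)cc1"))
  expect_equal(names(dv), descriptor_names())
  expect_length(dv, 60)
  expect_false(anyNA(dv))
  set.seed(3)
  for (s in c("CC(=O)Nc1ccc(O)cc1", "C1CC2CCC1C2", "OCC1OC(O)C(O)C(O)C1O")) {
    m <- parse_smiles(s)
    p <- permute_atoms(m, sample(n_atoms(m)))
    expect_equal(unname(compute_descriptors(p)), unname(compute_descriptors(m)),
                 tolerance = 1e-9, label = paste("invariance", s))
  }
})

test_that("internal identities hold on fixtures and generated molecules", {
  mols <- c(fixture_mols(), test_library("naturallike", n = 30, seed = 61))
  single <- Filter(function(m) n_components(m) == 1L, mols)
  for (m in single) {
    dv <- compute_descriptors(m, which = c(
      "SC0", "SC1", "SC3CH", "N_Atom", "N_Bonds", "N_R3", "N_R4", "N_R5",
      "N_R6", "N_R7", "N_R8", "N_R9+", "N_Rings", "N_aromatic", "N_Ringb",
      "N_AR", "N_BHA"))
    expect_equal(dv[["SC0"]], dv[["N_Atom"]])
    expect_equal(dv[["SC1"]], dv[["N_Bonds"]])
    expect_equal(dv[["SC3CH"]], dv[["N_R3"]])
    expect_equal(sum(dv[c("N_R3", "N_R4", "N_R5", "N_R6", "N_R7", "N_R8", "N_R9+")]),
                 dv[["N_Rings"]])
    expect_lte(dv[["N_aromatic"]], dv[["N_Ringb"]])
    expect_lte(dv[["N_Ringb"]], dv[["N_Bonds"]])
    expect_lte(dv[["N_AR"]], dv[["N_Rings"]])
    expect_lte(dv[["N_BHA"]], dv[["N_Atom"]])
  }
})

test_that("oxygen/nitrogen means separate the natural and drug-like classes", {
  nat <- compute_descriptor_table(test_library("naturallike", n = 150, seed = 71),
                                  which = c("N_O", "N_N"))
  drug <- compute_descriptor_table(test_library("druglike", n = 150, seed = 72),
                                   which = c("N_O", "N_N"))
  expect_gt(mean(nat$N_O), mean(drug$N_O))
  expect_lt(mean(nat$N_N), mean(drug$N_N))
})

test_that("descriptor tables carry names, NA-for-flagged and a flags column", {
  mols <- lapply(c("c1ccccc1", "CCO"), parse_smiles)
  tab <- compute_descriptor_table(mols, which = c("MW", "UNC_C3"))
  expect_equal(nrow(tab), 2)
  expect_true(is.na(tab$UNC_C3[1]))      # benzene: no sp3 carbon
  expect_match(tab$flags[1], "UNC_C3")
  expect_false(is.na(tab$UNC_C3[2]))
  expect_error(compute_descriptors(parse_smiles("C"), which = "nope"),
               "unknown descriptor")
})
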