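# Shared fixtures and independent oracles used across the test files.

# A diverse fixture set: hydrocarbons, heteroaromatics, fused/bridged/spiro
# systems, charged species and multi-component records.
fixture_smiles <- function() c(
  "C", "CC", "CCC", "CCCC", "CC(C)C", "CC(C)(C)C", "CCCCCC",
  "C1CC1", "C1CCC1", "C1CCCCC1", "C1CCCCCC1",
  "c1ccccc1", "Cc1ccccc1", "c1ccncc1", "c1cncnc1", "c1ccoc1", "c1cc[nH]c1",
  "c1ccc2ccccc2c1", "c1ccc2[nH]ccc2c1", "c1ccc(-c2ccccc2)cc1",
  "C1CC2CCC1C2", "C1CCC2CCCCC2C1", "C1CCC2(C1)CCCC2", "C1C2CC3CC1CC(C2)C3",
  "C1CC2CCC1CC2", "C1CC2CCC1O2",
  "CCO", "CCOCC", "CC(=O)O", "CC(N)=O", "CC=O", "CC(=O)Cl", "CC#N",
  "C=CC=C", "CC=CC", "FC(Cl)Br", "C(Cl)(Cl)Cl", "CS(C)=O", "CS(C)(=O)=O",
  "OCC1OC(O)C(O)C(O)C1O", "CC(=O)Oc1ccccc1C(=O)O", "CC(=O)Nc1ccc(O)cc1",
  "C(C(=O)[O-])[NH3+]", "CC(=O)O.[Na+]", "c1ccc(N2CCNCC2)cc1"
)

fixture_mols <- function() lapply(fixture_smiles(), parse_smiles)

# Exhaustive connected-subgraph enumeration: the independent oracle for the
# Kier & Hall counts. Classifies every 2- and 3-edge subset by shape.
enumerate_subgraph_counts <- function(mol) {
  B <- n_bonds(mol)
  bf <- mol$bond_from; bt <- mol$bond_to
  sc2 <- 0L; sc3p <- 0L; sc3c <- 0L; sc3ch <- 0L
  if (B >= 2L) {
    for (i in seq_len(B - 1L)) for (j in (i + 1L):B) {
      if (length(unique(c(bf[c(i, j)], bt[c(i, j)]))) == 3L) sc2 <- sc2 + 1L
    }
  }
  if (B >= 3L) {
    for (i in seq_len(B - 2L)) for (j in (i + 1L):(B - 1L)) for (k in (j + 1L):B) {
      atoms <- c(bf[c(i, j, k)], bt[c(i, j, k)])
      u <- unique(atoms)
      occ <- sort(tabulate(match(atoms, u)), decreasing = TRUE)
      if (length(u) == 3L && all(occ == 2L)) sc3ch <- sc3ch + 1L
      else if (length(u) == 4L && occ[1] == 3L) sc3c <- sc3c + 1L
      else if (length(u) == 4L && occ[1] == 2L) sc3p <- sc3p + 1L
    }
  }
  c(SC2 = sc2, SC3P = sc3p, SC3C = sc3c, SC3CH = sc3ch)
}

# O(n^2) brute-force threshold scan: the independent oracle for grid search.
brute_force_best_ga <- function(pos, neg) {
  vals <- sort(unique(c(pos, neg)))
  cuts <- c(vals[1] - 1, (vals[-length(vals)] + vals[-1]) / 2,
            vals[length(vals)] + 1)
  total <- length(pos) + length(neg)
  best <- 0
  for (t in cuts) {
    ga_below <- (sum(pos < t) + sum(neg >= t)) / total
    ga_above <- (sum(pos > t) + sum(neg <= t)) / total
    best <- max(best, ga_below, ga_above)
  }
  best
}

# cached small synthetic libraries shared across test files
.test_cache <- new.env()
test_library <- function(class, n = 150L, seed = 101L) {
  key <- paste(class, n, seed)
  if (is.null(.test_cache[[key]]))
    .test_cache[[key]] <- generate_library(library_spec(class, n = n, rng_seed = seed))
  .test_cache[[key]]
}
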