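# druglike

Property-based drug-likeness profiling of small-molecule libraries in R.

## The problem

Early drug discovery triages enormous compound collections with cheap,
property-based rules before anything is synthesised or assayed: Lipinski's
Rule-of-Five, ring/rigid-bond boxes, or single-descriptor cutoffs such as a
threshold on the fractional negatively charged water-accessible surface area
(FASA⁻). Evaluating such filters requires a reproducible pipeline that can
(i) curate raw vendor or natural-product libraries, (ii) compute a consistent
descriptor panel from 2D structures, (iii) score any candidate filter against
labelled reference sets, and (iv) compare whole libraries in descriptor space.
`druglike` implements that pipeline end to end for users who want to profile
their own libraries, and ships a seeded synthetic compound generator so every
stage can be exercised and tested without access to proprietary databases
(commercial screening collections, drug databases, natural-product archives).

## What it computes

* **Molecular graphs** — an in-package SMILES/SDF (V2000) reader producing
  hydrogen-suppressed graphs with formal charges, Hückel-style aromaticity
  perception, ring perception (SSSR, ring assemblies, spiro atoms, bridged
  systems), iterative PEOE (Gasteiger–Marsili) partial charges
  `χᵢ = aᵢ + bᵢqᵢ + cᵢqᵢ²` with damping `0.5^k`, and a conformation-free
  additive surface-area scheme (Bondi spheres minus per-neighbour spherical
  caps, probe radius 1.4 Å).
* **Curation** — the standard preprocessing protocol: valence check, salt and
  solvent stripping, element filter (C,H,O,N,P,S,F,Cl,Br,I), largest-fragment
  selection, canonical-key deduplication, cross-library deduplication, a
  12-pattern reactive-group filter, MW cutoffs, and molecular-weight-matched
  subset construction by seeded histogram matching.
* **Descriptors** — the 44-descriptor panel (AlogP, logD₇.₄, logS, MW,
  H-bond counts, rotatable bonds, TPSA, atom/bond/ring/chain/stereo counts,
  Kier & Hall subgraph counts SC0–SC3CH) plus 16 size-independent ratio
  descriptors (f_rot, f_PSA, the FASA/FVSA families, C3P, UNC_C3).
* **Filters** — Rule-of-Five with the ≤1-violation allowance
  (violations over MW > 500, AlogP > 5, N_HBDL > 5, N_HBAL > 10), the
  ring-count/rigid-bond box rule, and arbitrary single-descriptor threshold
  filters.
* **Screening evaluation** — confusion counts; SE, SP, PRE1, PRE2, global
  accuracy GA = (TP+TN)/N and the Matthews coefficient
  C = (TP·TN − FN·FP)/√((TP+FN)(TP+FP)(TN+FN)(TN+FP)); exhaustive
  threshold grid search per descriptor; descriptor ranking.
* **Profiling** — per-library distribution tables, pairwise mean differences
  and Kolmogorov–Smirnov statistics, OLS/Pearson correlation, and
  correlation-matrix PCA with pooled-basis score-plot panels.

## Worked example

```r
library(druglike)

# three seeded synthetic classes: drug-like, reagent-like, natural-like
bench <- generate_labeled_benchmark(n_per_class = 500, seed = 42)
drug <- bench$libraries$druglike
reag <- bench$libraries$reagentlike

# curate and describe
drug <- curate_library(drug)
tab_d <- compute_descriptor_table(drug, which = c("MW", "AlogP", "N_HBDL",
                                                  "N_HBAL", "FASA-"))
tab_r <- compute_descriptor_table(curate_library(reag),
                                  which = c("MW", "AlogP", "N_HBDL",
                                            "N_HBAL", "FASA-"))

# Rule-of-Five pass rate of the drug-like class
ro5_cols <- c("MW", "AlogP", "N_HBDL", "N_HBAL")
pass <- vapply(seq_len(nrow(tab_d)), function(i)
  rule_of_five(unlist(tab_d[i, ro5_cols]))$druglike, logical(1))
mean(pass)
#> [1] 0.992

# how well does the FASA- descriptor separate the two classes?
g <- grid_search_threshold(tab_d[["FASA-"]], tab_r[["FASA-"]],
                           descriptor_name = "FASA-")
g$filter
#> <threshold_filter: FASA- < 0.321874>
round(g$metrics[["GA"]], 3)
#> [1] 0.703
```

The grid search recovers a "small FASA⁻ is drug-like" rule with a cutoff
near 0.32 and a global accuracy of about 0.70 on these two synthetic
classes: the drug-like class (aromatic- and nitrogen-rich) exposes less
negatively charged surface than the carbonyl- and halogen-rich reagent
class, so a single surface-charge threshold carries real but modest
classification power — the behaviour such filters show on real libraries.

## Command line

A thin wrapper over the same functions is installed at `exec/druglike`:

```sh
druglike simulate --class naturallike --n 1000 --seed 42 --out nat.smi
druglike curate   --in nat.smi --out curated.smi --report report.csv --mw-cutoff 600
druglike describe --in curated.smi --out desc.csv
druglike screen   --desc pos.csv --neg neg.csv --out ranking.csv
```

## Scope notes

Descriptor values are reconstructions of the standard definitions from 2D
graphs; they are not numerically identical to any commercial implementation
(logD₇.₄ and logS in particular are declared linear surrogates with editable
coefficient tables under `inst/extdata/`). See the methods vignette
(`vignettes/drug-likeness-profiling.Rmd`) for the models, parameter choices
and limitations.
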