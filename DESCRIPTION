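Package: druglike
Title: Property-Based Drug-Likeness Profiling of Compound Libraries
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Curation, descriptor calculation and drug-likeness profiling of
    small-molecule libraries from 2D molecular graphs. Parses SMILES and SDF
    records into hydrogen-suppressed molecular graphs; perceives rings
    (SSSR, ring assemblies, spiro and bridged systems) and aromaticity;
    computes iterative partial-equalisation-of-orbital-electronegativity
    (PEOE) charges and conformation-free approximate atomic surface areas;
    evaluates a 60-descriptor panel (atom-contribution logP, topological
    polar surface area, hydrogen-bonding counts, ring/chain/stereo counts,
    Kier & Hall subgraph counts, fractional charged-surface descriptors);
    applies property-based drug-likeness rules (Lipinski Rule-of-Five,
    ring/rigid-bond boxes, single-descriptor threshold filters found by
    exhaustive grid search and scored by confusion-matrix statistics
    including the Matthews correlation coefficient); builds molecular-weight
    matched subsets; and profiles libraries by distribution summaries and
    standardized principal component analysis. A seeded fragment-based
    generator of drug-like, reagent-like and natural-product-like compound
    classes makes the whole pipeline testable without proprietary databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    utils,
    jsonlite,
    tibble,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
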