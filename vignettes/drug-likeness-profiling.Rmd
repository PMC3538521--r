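---
title: "Profiling compound libraries with property-based drug-likeness filters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling compound libraries with property-based drug-likeness filters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(druglike)
```

`druglike` evaluates property-based drug-likeness filters on compound
libraries: it curates raw libraries, computes a 60-descriptor panel from 2D
molecular graphs, scores filters by confusion-matrix statistics, and
compares libraries by distribution tables and principal component analysis.
This vignette is the package's account of the underlying models: what is
computed, which parameters matter, what the synthetic benchmark does and
does not emulate, and where the reconstructions have known limits.

## The molecular data model

All computation starts from a hydrogen-suppressed molecular graph: atoms
carry an element, a formal charge, an implicit-hydrogen count and an
aromatic flag; bonds carry an integer order and an aromatic flag. The
package parses SMILES (organic subset, bracket atoms, ring closures,
multi-fragment records) and V2000 SDF connection tables, including `M CHG`
formal-charge blocks. Two perception steps normalise the graph:

* **Rings.** An SSSR (a minimum cycle basis) is built from Horton candidate
  cycles — the shortest cycle through each ring bond via each ring atom —
  selected greedily by linear independence over GF(2) in order of size, so
  `|SSSR| = bonds − atoms + components` always holds. Rings sharing at least
  one atom are grouped into *assemblies*; an assembly is *bridged* when some
  ring pair shares more than one bond (norbornane, adamantane), and an atom
  shared by two rings with no other common atom is a *spiro* atom.
* **Aromaticity.** Lowercase SMILES atoms are trusted; kekulized input is
  additionally flagged by a Hückel-style rule over SSSR rings: every ring
  atom must be π-capable (in-ring double bond → 1 electron; exocyclic
  multiple bond → 0; N/O/S lone pair → 2; saturated carbon → not capable)
  and the ring total must be 4n+2. This fixed, documented model matches the
  common cases (benzene, pyridine, pyrrole, furan, fused aromatics) and
  deliberately attempts nothing exotic (no charged carbon rings, no
  tautomer-dependent calls).

Validity is checked against allowed valences (C 4; N 3/5, N⁺ 4; O 2, O⁻ 1;
S 2/4/6; P 3/5; halogens 1) with aromatic atoms checked by σ-connection
count. Parse failures and valence violations are typed, loggable errors,
never crashes.

## Partial charges and surface areas

Fractional-surface descriptors need per-atom charges and areas.

* **Charges** are classical PEOE (partial equalisation of orbital
  electronegativities): electronegativity is the quadratic
  `χᵢ = aᵢ + bᵢqᵢ + cᵢqᵢ²` with published element/hybridisation parameters;
  at iteration *k* charge flows across each bond from the less to the more
  electronegative atom, normalised by the donor's cation electronegativity
  and damped by `0.5^k`. Six iterations with tolerance 1e-6 are the default
  (the classical scheme); formal charges seed the iteration so total charge
  is conserved exactly. Hydrogens are expanded and charged individually.
  Phosphorus and sulfur use commonly adopted parameter extensions.
* **Areas** use a deliberately simple, conformation-free additive scheme:
  each atom is a sphere with its Bondi van der Waals radius (plus a 1.4 Å
  water-probe radius for the accessible variant); each bonded neighbour
  removes a spherical cap evaluated at an idealised bond length (sum of
  covalent radii, shortened ×0.92/×0.87/×0.78 for aromatic/double/triple
  bonds). An isolated atom's accessible area is exactly `4π(r + 1.4)²`.
  Absolute areas from such a scheme are approximate by construction; the
  descriptors consuming them are *fractions* of the total surface, which is
  why this reconstruction is defensible where a 3D method is not available.

The **FASA family** partitions the accessible surface by charge sign:
`FASA⁺`/`FASA⁻` are the area fractions of atoms with positive/negative PEOE
charge. An exactly zero charge contributes to neither bucket; an internal
third bucket closes the partition, so `FASA⁺ + FASA⁻ ≤ 1` with equality in
the generic case. `FASA_P` covers polar atoms (N, O, S, P and their
hydrogens) with `FASA_H` its complement; `FCASA±` weight areas by |q|; the
`FVSA` set repeats all definitions on van der Waals areas.

## The descriptor panel

The 44 base descriptors and 16 ratio descriptors are reconstructions of
their standard, name-level definitions — no commercial implementation is
reproduced numerically. Decisions worth knowing:

* `N_Atom`, `N_Bonds` and all subgraph counts are heavy-atom quantities; MW
  includes hydrogens and uses average atomic masses (the classic 600/800 Da
  cutoffs do not specify a mass convention; average masses are the common
  reading).
* Lipinski counts: `N_HBDL` = hydrogens on N/O, `N_HBAL` = number of N+O
  atoms. The generic `N_HBA` excludes pyrrole-type aromatic nitrogens,
  amide nitrogens and positively charged nitrogens.
* `N_rot`: single, non-ring, non-aromatic bonds between non-terminal heavy
  atoms, excluding amide C–N.
* `N_Stereo`: sp3 carbons with four connections whose substituents
  (hydrogen counted) fall in pairwise distinct symmetry classes, computed by
  Morgan/Weisfeiler–Lehman refinement; `N_StereoB`: non-ring C=C bonds with
  two distinct substituents on each end. Symmetry classes approximate atom
  orbits, which is the standard graph-level notion of "potential
  stereocentre" — no 3D parities are assigned.
* `N_Chains` counts non-ring atoms *including hydrogens* while `N_ChainA`
  is its heavy-atom variant. The name-level definition is ambiguous; this
  reading is fixed here because reported means of the two differ by roughly
  the hydrogen count, and it is flagged as a reconstruction.
* Kier & Hall subgraph counts are closed-form (`SC2 = Σ C(dᵢ,2)`,
  `SC3C = Σ C(dᵢ,3)`, triangles from common neighbours, three-edge paths by
  inclusion–exclusion) and are tested against exhaustive subgraph
  enumeration; the identities `SC0 = N_Atom`, `SC1 = N_Bonds`,
  `SC3CH = N_R3` hold by construction.
* `AlogP` is a Crippen-style additive atom-contribution model with a
  condensed 26-type table shipped as an editable CSV
  (`inst/extdata/crippen_logp.csv`). `PSA` is the Ertl fragment-contribution
  topological PSA over N/O environments. `logD7.4` and `logS` are declared
  *surrogates*: logD subtracts per-group ionisation penalties
  `log10(1 + 10^(7.4 − pKa))` (acids) or `log10(1 + 10^(pKa − 7.4))`
  (bases) for recognised carboxylic/sulfonic acids and aliphatic amines;
  logS is a linear model over AlogP, MW, rotatable bonds and aromatic bonds
  with ESOL-flavoured default coefficients. All coefficient tables are
  plain-text configuration so published alternatives can be substituted.
* Ratio descriptors with zero denominators (e.g. `UNC_C3` of benzene, which
  has no sp3 carbon) return 0 *plus a flag*; tables encode them as `NA` with
  a companion `flags` column, and the screening code excludes them with a
  count rather than propagating `NaN`.

## Curation

`curate_library()` applies the standard preprocessing protocol in order:
(1) drop valence-invalid molecules; (2) strip known salt counter-ion
fragments; (3) drop molecules with elements outside C,H,O,N,P,S,F,Cl,Br,I;
(4) strip known solvent fragments; (5) keep the largest connected fragment;
(6) deduplicate by canonical structure key. Salt/solvent lists are editable
JSON (the protocol's own lists are not enumerated anywhere); fragments are
only stripped while another component remains, and step 5 is the safety net
for anything the lists miss. The duplicate key is an order-invariant
Weisfeiler–Lehman key over atoms, bonds and recorded chirality tags: it
keeps stereo distinctions (natural products often differ only there) but
does not canonicalise parity, so distinct encodings of the *same*
stereoisomer can evade deduplication — a conservative failure mode. The
12 reactive groups (aldehyde, alkyl-halide, anhydride, diazo, dicarbonyl,
disulfide, hydrazine-N-NH2, isocyanate, isothiocyanate, peroxide, quaternary
amine, acyl-halide) are in-code graph patterns matched by a backtracking
subgraph matcher; the encodings are this package's own and editable.

**MW-matched subsets** remove size confounding before comparing libraries:
both sets are binned by MW (default 20 Da), and each candidate bin is
sampled without replacement proportionally to the reference bin's relative
frequency, scaled so no bin is over-drawn; the RNG seed is part of the
specification, so subsets are reproducible. The original matching protocol
is not public; histogram matching is documented as a reconstruction. Finer
bins (10 Da) trade subset size for distribution-level agreement and are
used where a Kolmogorov–Smirnov-level match matters.

## Filters and screening evaluation

`rule_of_five()` counts violations over MW > 500, AlogP > 5, N_HBDL > 5,
N_HBAL > 10 and calls a molecule drug-like at ≤ 1 violation. `oprea_box()`
classifies by ring count RNG and rigid bonds RGB: RGB is taken as
heavy-atom bonds minus rotatable bonds (the original rigid-bond definition
differs in terminal-bond treatment; this reading is documented).
`apply_threshold()` is strict: ties at the cutoff are negative, and
flagged-undefined values classify negative with a warning.

`grid_search_threshold()` scans candidate cutoffs at the midpoints of
adjacent distinct pooled values plus one cutoff beyond each extreme — an
exhaustive scan over all achievable strict-threshold classifications, which
dominates any fixed-step grid — in both directions, maximising GA (default)
or the Matthews coefficient; ties break toward the smaller cutoff, then
toward "below is positive". The implementation is O(n log n) via sorted
rank counting and is tested for exact agreement with an O(n²) brute-force
scan. PRE1/PRE2 are the positive/negative predictive values TP/(TP+FP) and
TN/(TN+FN); statistics with zero denominators are flagged `NA`, and the
Matthews coefficient is ±1 exactly for perfect/anti-perfect tables.

## Profiling and PCA

`profile_library()` reports per-descriptor means, sample SDs and
histograms (default bin widths: 50 Da for MW, 0.5 for logP-type scales,
10 Å² for surface areas). `compare_libraries()` adds pairwise mean
differences and two-sample KS statistics from the raw columns. `run_pca()`
standardises every column to zero mean and unit variance (correlation-matrix
PCA — the descriptors span wildly different scales and the source analyses
do not state a scaling, so the scale-free choice is made explicitly), drops
constant columns, imputes flagged values with the column mean (preserving
standardisation), and fixes each loading's sign so its largest-magnitude
entry is positive. Score plots project every library onto one basis fitted
on the pooled table, so panels are comparable — the natural reading of
cross-library component plots.

## The synthetic benchmark

`generate_labeled_benchmark()` emulates three classes of compound library
so the pipeline is testable without proprietary collections:

* **drug-like** — aromatic/heteroaromatic scaffolds with amine, amide,
  sulfonamide, halogen and ether substituents; MW window 340–470 Da
  (mean ≈ 405, matching the ≈400 Da reported for drug-like libraries);
* **reagent-like** — small acyclic/monocyclic scaffolds rich in acids,
  aldehydes, acyl/alkyl halides and esters; window 200–340 Da (mean ≈ 270);
* **natural-product-like** — fused/bridged sp3 scaffolds (decalin-,
  norbornane-, adamantane-, steroid- and pyranose-like) dominated by
  hydroxyl substituents; window 300–440 Da (mean ≈ 370), nitrogen-free,
  stereocentre- and bridged-ring-rich.

Each molecule draws a scaffold, then attaches weighted substituents at
uniformly chosen open valences until the molecular weight reaches a target
drawn uniformly inside the class window (so libraries spread across their
windows rather than piling at the lower edge). Heteroatom–heteroatom
couplings are skipped (no accidental peroxides/hydrazines), and single-atom
halogens attach to aromatic carbons when the scaffold offers any, so the
drug-like class carries aryl rather than alkyl halides; its residual
reactive fraction (~5%, from low-weight chloromethyl/formyl substituents)
mirrors the minority reactive fraction reported for real drug-like
collections. Everything is driven by R's Mersenne-Twister RNG under an
explicit seed: generation is deterministic and byte-identical across runs.

The emulation targets are *qualitative*: the sign pattern of the class
contrasts (natural vs drug-like: more oxygens, fewer nitrogens, fewer
rotatable bonds, fewer aromatic bonds, more bridged-ring bonds, more
stereocentres; reagent-like vs drug-like: lower MW, fewer rings) and the
designed property that the FASA⁻ descriptor separates drug-like from
reagent-like with modest global accuracy (~0.67–0.70 at 400–600 molecules
per class) while two same-class samples are inseparable (GA ≈ 0.5).
Fragment weights were fixed during a one-time calibration at a few hundred
molecules per class and are shipped as configuration
(`inst/extdata/fragments.json`); they were not revisited afterwards. What
passing tests on this benchmark shows is that the *pipeline* — curation,
descriptors, screening, matching, PCA — behaves correctly on libraries with
realistic contrast structure; it says nothing quantitative about any real
database, whose absolute descriptor means, correlations between descriptors
and synthetic-accessibility characteristics the generator does not attempt
to reproduce.

## Numerical choices and degenerate inputs

* Threshold ties are negative everywhere (strict `<`/`>`).
* Grid-search candidate cutoffs never coincide with data values
  (midpoints of adjacent distinct values), so strict comparison is exact.
* Zero-denominator statistics and descriptors are flagged, never silent
  `NaN`; screening excludes flagged values with a reported count.
* Empty libraries, empty files, single-value columns and constant PCA
  columns raise typed errors or degrade gracefully (documented per
  function).
* Problem sizes in the shipped tests: fixture molecules ≤ 50 atoms; oracle
  equivalence on all fixtures ≤ 12 heavy atoms; grid-search oracle at
  200+200 × 100 instances; MW matching at 10,000 + 10,000 molecules;
  class contrasts at 2,000 per class; PCA sanity at n = 10,000. These sizes
  were chosen to make the statistical assertions stable under the fixed
  seeds while keeping a full test run in a few minutes.

## Known limitations

* Descriptor values are 2D reconstructions: no conformers, no 3D surface
  areas, no quantum charges. Comparisons against numbers produced by
  commercial 3D implementations are meaningful at the level of ranks,
  fractions and contrasts, not absolute values.
* logD₇.₄ recognises three ionisable-group families; zwitterions and
  unusual acids/bases outside them are treated as neutral.
* The WL duplicate key can in principle collide for
  Weisfeiler–Lehman-indistinguishable graph pairs (not observed for
  ordinary organic molecules at these sizes) and does not canonicalise
  stereo parity.
* Aromaticity perception is single-model and non-tautomer-aware.
* The generator makes no claim of synthetic accessibility or
  medicinal-chemistry plausibility for individual molecules.
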