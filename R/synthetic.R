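# Seeded fragment-based generator of three synthetic compound classes.
#
# The generator exists so the whole pipeline can be exercised and tested
# without proprietary compound databases. Each class draws a scaffold and
# grows it by attaching substituents at open valences until the molecular
# weight enters the class window. The fragment sets (inst/extdata/
# fragments.json) are chosen so the classes reproduce, in sign, the
# qualitative contrasts reported between reagent-like, drug-like and
# natural-product-like libraries: drug-like is nitrogen- and aromatic-rich
# around MW 400; reagent-like is small with few rings; natural-like is
# oxygen-rich, nitrogen-poor, sp3- and bridged-ring-rich with few rotatable
# bonds and many stereocentres. The emulation is qualitative by design; no
# attempt is made to match absolute descriptor means of any real database.

#' Specification of one synthetic compound class
#'
#' @param class `"druglike"`, `"reagentlike"` or `"naturallike"`.
#' @param n number of molecules to generate.
#' @param rng_seed integer seed (used by [generate_library()]).
#' @param mw_window optional `c(low, high)` MW window in Da overriding the
#'   class default.
#' @param fragment_weights optional list with `scaffolds` and `substituents`
#'   named-weight vectors overriding the class defaults.
#' @return object of class `library_spec`.
#' @export
library_spec <- function(class = c("druglike", "reagentlike", "naturallike"),
                         n = 1000L, rng_seed = 1L, mw_window = NULL,
                         fragment_weights = NULL) {
  class <- match.arg(class)
  cfg <- config_json("fragments.json")[[class]]
  if (is.null(mw_window)) mw_window <- as.numeric(cfg$mw_window)
  stopifnot(n > 0, length(mw_window) == 2L, mw_window[1] < mw_window[2])
  fw <- fragment_weights %||% list(scaffolds = unlist(cfg$scaffolds),
                                   substituents = unlist(cfg$substituents))
  stopifnot(all(fw$scaffolds > 0), all(fw$substituents > 0))
  structure(list(class = class, n = as.integer(n), rng_seed = as.integer(rng_seed),
                 mw_window = mw_window, fragment_weights = fw),
            class = "library_spec")
}

# parse and cache fragment graphs + MW for a spec
fragment_sets <- function(spec) {
  key <- paste0("frag:", spec$class, ":",
                length(spec$fragment_weights$scaffolds), ":",
                length(spec$fragment_weights$substituents))
  if (is.null(.druglike_cache[[key]])) {
    prep <- function(w) {
      mols <- lapply(names(w), parse_smiles)
      list(mols = mols,
           mw = vapply(mols, molecular_weight, numeric(1)),
           prob = unname(w / sum(w)))
    }
    .druglike_cache[[key]] <- list(
      scaffolds = prep(spec$fragment_weights$scaffolds),
      substituents = prep(spec$fragment_weights$substituents))
  }
  .druglike_cache[[key]]
}

# attach frag's first atom to mol's `site` atom with a single bond
graft <- function(mol, site, frag) {
  off <- n_atoms(mol)
  molgraph(
    element = c(mol$element, frag$element),
    charge = c(mol$charge, frag$charge),
    nH = { h <- c(mol$nH, frag$nH); h[site] <- h[site] - 1L; h[off + 1L] <- h[off + 1L] - 1L; h },
    aromatic = c(mol$aromatic, frag$aromatic),
    bond_from = c(mol$bond_from, frag$bond_from + off, site),
    bond_to = c(mol$bond_to, frag$bond_to + off, off + 1L),
    bond_order = c(mol$bond_order, frag$bond_order, 1L),
    bond_aromatic = c(mol$bond_aromatic, frag$bond_aromatic, FALSE),
    chiral = c(mol$chiral, frag$chiral),
    name = mol$name
  )
}

HETERO_SET <- c("N", "O", "S", "P")

#' Sample one synthetic molecule
#'
#' Draws a scaffold from the class's weighted scaffold set, then attaches
#' weighted substituents at uniformly chosen open valences (atoms with a
#' spare hydrogen; heteroatom-heteroatom attachments are skipped) until the
#' molecular weight enters the spec's window. Uses the current R random
#' number generator state; seed control belongs to [generate_library()].
#'
#' @param spec a [library_spec()].
#' @param max_attempts molecule-level retries before giving up.
#' @return a [molgraph()].
#' @export
sample_molecule <- function(spec, max_attempts = 50L) {
  fs <- fragment_sets(spec)
  lo <- spec$mw_window[1]; hi <- spec$mw_window[2]
  mh <- atomic_masses()[["H"]]
  for (attempt in seq_len(max_attempts)) {
    si <- sample.int(length(fs$scaffolds$mols), 1L, prob = fs$scaffolds$prob)
    mol <- fs$scaffolds$mols[[si]]
    mw <- fs$scaffolds$mw[si]
    # per-molecule target spreads the library across the whole window
    target <- stats::runif(1, lo, hi)
    ok <- TRUE
    guard <- 0L
    while (mw < target) {
      guard <- guard + 1L
      if (guard > 60L) { ok <- FALSE; break }
      fi <- sample.int(length(fs$substituents$mols), 1L, prob = fs$substituents$prob)
      frag <- fs$substituents$mols[[fi]]
      new_mw <- mw + fs$substituents$mw[fi] - 2 * mh
      if (new_mw > hi) next
      sites <- which(mol$nH >= 1L)
      # no heteroatom-heteroatom couplings (avoids accidental peroxides etc.)
      if (frag$element[1] %in% HETERO_SET)
        sites <- sites[!mol$element[sites] %in% HETERO_SET]
      # halogens go on aromatic carbons when the scaffold offers any (aryl
      # halides); purely aliphatic scaffolds keep their alkyl halides
      if (frag$element[1] %in% c("F", "Cl", "Br", "I") && length(frag$element) == 1L &&
          any(mol$aromatic[sites]))
        sites <- sites[mol$aromatic[sites]]
      if (!length(sites)) { ok <- FALSE; break }
      site <- sites[sample.int(length(sites), 1L)]
      mol <- graft(mol, site, frag)
      mw <- new_mw
    }
    if (ok && mw >= lo && mw <= hi) {
      return(mol)
    }
  }
  stop("could not reach the MW window in ", max_attempts, " attempts")
}

#' Generate a synthetic compound library
#'
#' Deterministic for a given spec: the spec's seed initialises the RNG and
#' the previous RNG state is restored afterwards.
#' @param spec a [library_spec()].
#' @return list of [molgraph()] objects of length `spec$n`, named
#'   `<class>_<i>`.
#' @export
generate_library <- function(spec) {
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(spec$rng_seed)
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  mols <- vector("list", spec$n)
  for (i in seq_len(spec$n)) {
    m <- sample_molecule(spec)
    m$name <- sprintf("%s_%d", spec$class, i)
    mols[[i]] <- m
  }
  mols
}

#' Generate the three-class labelled benchmark
#'
#' One library per class (equal size), written as SMILES files plus a labels
#' CSV when `dir` is given. Byte-identical across runs for a given seed.
#' @param n_per_class molecules per class.
#' @param seed integer master seed (per-class seeds are derived as
#'   `seed`, `seed + 1`, `seed + 2`).
#' @param dir optional output directory for `druglike.smi`, `reagentlike.smi`,
#'   `naturallike.smi` and `labels.csv`.
#' @return list with `libraries` (named list of molecule lists), `labels`
#'   (tibble with `name`, `class`) and `files` (paths or NULL).
#' @export
generate_labeled_benchmark <- function(n_per_class, seed = 1L, dir = NULL) {
  stopifnot(n_per_class > 0)
  classes <- c("druglike", "reagentlike", "naturallike")
  libs <- list()
  for (k in seq_along(classes)) {
    spec <- library_spec(classes[k], n = n_per_class, rng_seed = seed + k - 1L)
    libs[[classes[k]]] <- generate_library(spec)
  }
  labels <- tibble::tibble(
    name = unlist(lapply(libs, function(l) vapply(l, function(m) m$name, character(1)))),
    class = rep(classes, each = n_per_class))
  files <- NULL
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    files <- c(vapply(classes, function(cl) {
      p <- file.path(dir, paste0(cl, ".smi"))
      write_library(libs[[cl]], p)
      p
    }, character(1)), labels = file.path(dir, "labels.csv"))
    utils::write.csv(labels, files[["labels"]], row.names = FALSE)
  }
  list(libraries = libs, labels = labels, files = files)
}
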