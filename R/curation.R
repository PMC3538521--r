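# Library curation: the sequential preprocessing protocol (valence check,
# salt stripping, element filter, solvent stripping, largest fragment,
# in-library deduplication), cross-library deduplication, reactive-group
# flagging, molecular-weight cutoffs and MW-distribution-matched subsets.

salt_solvent_keys <- function(what = c("salt", "solvent")) {
  what <- match.arg(what)
  key <- paste0("keys:", what)
  if (is.null(.druglike_cache[[key]])) {
    smis <- if (what == "salt") salt_fragments() else solvent_fragments()
    .druglike_cache[[key]] <- vapply(smis, function(s) canonical_key(parse_smiles(s)),
                                     character(1))
  }
  .druglike_cache[[key]]
}

# strip components whose canonical key is in `keys`, provided at least one
# other component remains; returns list(mol, stripped_fragments)
strip_fragments <- function(mol, keys) {
  comp <- components(mol)
  ncomp <- max(comp)
  if (ncomp < 2L) return(list(mol = mol, stripped = 0L))
  comp_keys <- vapply(seq_len(ncomp), function(cid)
    canonical_key(keep_atoms(mol, which(comp == cid))), character(1))
  is_strip <- comp_keys %in% keys
  if (all(is_strip) || !any(is_strip)) return(list(mol = mol, stripped = 0L))
  keep <- which(!is_strip[comp])
  list(mol = keep_atoms(mol, keep), stripped = sum(is_strip))
}

#' Curate a compound library
#'
#' Applies the sequential preprocessing protocol: (1) drop molecules with
#' impossible valence states; (2) strip known salt counter-ion fragments;
#' (3) drop molecules containing elements outside C, H, O, N, P, S, F, Cl,
#' Br, I; (4) strip known solvent fragments; (5) keep the largest connected
#' fragment (by heavy-atom count); (6) remove duplicates within the library
#' by canonical structure key. Removals are reported, never raised. Salt and
#' solvent fragments are only stripped while another component remains; step
#' 5 is the safety net for anything the lists miss.
#'
#' @param mols list of [molgraph()] objects.
#' @param drop_reactive also remove molecules flagged by [flag_reactive()]
#'   (off by default, mirroring a protocol that surveys but keeps them).
#' @return list of curated molecules with attribute `report`, a data.frame
#'   with columns `step`, `description`, `molecules_removed`,
#'   `fragments_stripped`.
#' @export
curate_library <- function(mols, drop_reactive = FALSE) {
  report <- data.frame(
    step = c(1L, 2L, 3L, 4L, 5L, 6L, 7L),
    description = c("bad valence states", "salt fragments stripped",
                    "disallowed elements", "solvent fragments stripped",
                    "kept largest fragment", "in-library duplicates",
                    "reactive groups"),
    molecules_removed = 0L, fragments_stripped = 0L)
  input_size <- length(mols)

  ok <- vapply(mols, check_valence, logical(1))
  report$molecules_removed[1] <- sum(!ok)
  mols <- mols[ok]

  skeys <- salt_solvent_keys("salt")
  res <- lapply(mols, strip_fragments, keys = skeys)
  report$fragments_stripped[2] <- sum(vapply(res, `[[`, integer(1), "stripped") > 0L)
  mols <- lapply(res, `[[`, "mol")

  allowed <- elements_allowed()
  ok <- vapply(mols, function(m) all(m$element %in% allowed), logical(1))
  report$molecules_removed[3] <- sum(!ok)
  mols <- mols[ok]

  vkeys <- salt_solvent_keys("solvent")
  res <- lapply(mols, strip_fragments, keys = vkeys)
  report$fragments_stripped[4] <- sum(vapply(res, `[[`, integer(1), "stripped") > 0L)
  mols <- lapply(res, `[[`, "mol")

  multi <- vapply(mols, n_components, integer(1)) > 1L
  report$fragments_stripped[5] <- sum(multi)
  mols <- lapply(mols, function(m) {
    comp <- components(m)
    if (max(comp) == 1L) return(m)
    sizes <- tabulate(comp)
    keep_atoms(m, which(comp == which.max(sizes)))
  })

  keys <- vapply(mols, canonical_key, character(1))
  dup <- duplicated(keys)
  report$molecules_removed[6] <- sum(dup)
  mols <- mols[!dup]

  if (drop_reactive) {
    reactive <- vapply(mols, function(m) flag_reactive(m)$reactive, logical(1))
    report$molecules_removed[7] <- sum(reactive)
    mols <- mols[!reactive]
  }

  stopifnot(input_size - sum(report$molecules_removed) == length(mols))
  attr(mols, "report") <- report
  mols
}

#' Remove from one library the structures present in another
#'
#' @param libA,libB lists of [molgraph()] objects (curated).
#' @return `libA` without molecules whose canonical key occurs in `libB`;
#'   `libB` is untouched.
#' @export
cross_deduplicate <- function(libA, libB) {
  keysB <- vapply(libB, canonical_key, character(1))
  keysA <- vapply(libA, canonical_key, character(1))
  libA[!(keysA %in% keysB)]
}

#' Write a curation report as CSV
#' @param mols result of [curate_library()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_curation_report <- function(mols, path) {
  utils::write.csv(attr(mols, "report"), path, row.names = FALSE)
  invisible(path)
}

#' Molecular-weight cutoff
#'
#' Keeps molecules with MW strictly below `cutoff` (the protocol's "less
#' than" reading), order preserved.
#' @param mols list of [molgraph()] objects.
#' @param cutoff MW cutoff in Da (e.g. 600 or 800).
#' @return sublist.
#' @export
apply_mw_cutoff <- function(mols, cutoff) {
  stopifnot(cutoff > 0)
  mw <- vapply(mols, molecular_weight, numeric(1))
  mols[mw < cutoff]
}

#' Specification of a molecular-weight matching run
#' @param bin_width histogram bin width in Da (default 20).
#' @param rng_seed integer seed controlling within-bin sampling.
#' @param max_ratio maximum fraction of a candidate bin that may be drawn.
#' @return object of class `mw_match_spec`.
#' @export
mw_match_spec <- function(bin_width = 20, rng_seed = 1L, max_ratio = 1) {
  stopifnot(bin_width > 0, max_ratio > 0, max_ratio <= 1)
  structure(list(bin_width = bin_width, rng_seed = as.integer(rng_seed),
                 max_ratio = max_ratio), class = "mw_match_spec")
}

#' Build a molecular-weight-matched subset
#'
#' Histogram matching: both sets are binned by MW with the spec's bin width;
#' from each candidate bin a count proportional to the reference bin's
#' relative frequency is sampled without replacement, with the overall scale
#' chosen so that no bin demands more candidates than it has (times
#' `max_ratio`). Deterministic given the spec's seed.
#'
#' @param candidates,reference lists of [molgraph()] objects (non-empty).
#' @param spec a [mw_match_spec()].
#' @return sublist of `candidates` whose MW distribution matches the
#'   reference's.
#' @export
build_mw_matched_subset <- function(candidates, reference, spec = mw_match_spec()) {
  if (!length(reference)) stop("reference library is empty")
  if (!length(candidates)) stop("candidate library is empty")
  mw_c <- vapply(candidates, molecular_weight, numeric(1))
  mw_r <- vapply(reference, molecular_weight, numeric(1))
  bw <- spec$bin_width
  bin_c <- floor(mw_c / bw)
  bin_r <- floor(mw_r / bw)
  p_ref <- table(bin_r) / length(mw_r)
  n_cand <- table(bin_c)
  bins <- names(p_ref)[names(p_ref) %in% names(n_cand)]
  if (!length(bins)) return(candidates[integer()])
  # largest scale s with floor(s * p_b) <= max_ratio * n_b for every shared bin
  s <- min(as.numeric(n_cand[bins]) * spec$max_ratio / as.numeric(p_ref[bins]))
  take <- floor(s * as.numeric(p_ref[bins]))
  sel <- integer()
  old_seed <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(spec$rng_seed)
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  for (b in seq_along(bins)) {
    pool <- which(bin_c == as.numeric(bins[b]))
    k <- min(take[b], length(pool))
    if (k > 0L) sel <- c(sel, sort(pool[sample.int(length(pool), k)]))
  }
  candidates[sort(sel)]
}
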