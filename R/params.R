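# Element parameter tables and configuration loaders.
#
# Physical constants (masses, radii, PEOE electronegativity parameters) are
# fixed here; empirical coefficient tables (atom-contribution logP, TPSA
# fragments, logS regression, pKa values, reactive patterns, salt/solvent
# lists, generator fragment sets) ship as editable plain-text files under
# inst/extdata and are loaded lazily.

.druglike_cache <- new.env(parent = emptyenv())

config_path <- function(file) {
  p <- system.file("extdata", file, package = "druglike")
  if (!nzchar(p)) stop("configuration file not found: ", file)
  p
}

config_csv <- function(file) {
  key <- paste0("csv:", file)
  if (is.null(.druglike_cache[[key]])) {
    .druglike_cache[[key]] <- utils::read.csv(config_path(file), stringsAsFactors = FALSE,
                                              check.names = FALSE, comment.char = "#")
  }
  .druglike_cache[[key]]
}

config_json <- function(file) {
  key <- paste0("json:", file)
  if (is.null(.druglike_cache[[key]])) {
    .druglike_cache[[key]] <- jsonlite::read_json(config_path(file), simplifyVector = TRUE)
  }
  .druglike_cache[[key]]
}

#' Average atomic masses (Da)
#' @return named numeric vector.
#' @export
atomic_masses <- function() c(
  H = 1.008, B = 10.81, C = 12.011, N = 14.007, O = 15.999, F = 18.998,
  Na = 22.990, Mg = 24.305, Si = 28.085, P = 30.974, S = 32.06, Cl = 35.45,
  K = 39.098, Ca = 40.078, Fe = 55.845, Zn = 65.38, Se = 78.971,
  Br = 79.904, I = 126.904, Li = 6.94, Al = 26.982, As = 74.922,
  Sn = 118.71, Hg = 200.59
)

# Bondi van der Waals radii (Angstrom); Na/K for counter-ions
vdw_radii <- function() c(
  H = 1.20, B = 1.92, C = 1.70, N = 1.55, O = 1.52, F = 1.47, Na = 2.27,
  Mg = 1.73, Si = 2.10, P = 1.80, S = 1.80, Cl = 1.75, K = 2.75, Ca = 2.31,
  Br = 1.85, I = 1.98, Li = 1.82, Se = 1.90, Zn = 1.39
)

# single-bond covalent radii (Angstrom), used for idealized 2D bond lengths
covalent_radii <- function() c(
  H = 0.31, B = 0.84, C = 0.76, N = 0.71, O = 0.66, F = 0.57, Na = 1.66,
  Mg = 1.41, Si = 1.11, P = 1.07, S = 1.05, Cl = 1.02, K = 2.03, Ca = 1.76,
  Br = 1.20, I = 1.39, Li = 1.28, Se = 1.20, Zn = 1.22
)

# Gasteiger-Marsili PEOE parameters a, b, c by element and hybridisation
# class ("sp3", "sp2", "sp"); chi_plus is the cation electronegativity used
# to normalise transfers from the donor atom (20.02 for hydrogen).
peoe_parameters <- function() {
  p <- list(
    "H"     = c(7.17, 6.24, -0.56),
    "C.sp3" = c(7.98, 9.18, 1.88),
    "C.sp2" = c(8.79, 9.32, 1.51),
    "C.sp"  = c(10.39, 9.45, 0.73),
    "N.sp3" = c(11.54, 10.82, 1.36),
    "N.sp2" = c(12.87, 11.15, 0.85),
    "N.sp"  = c(15.68, 11.70, -0.27),
    "O.sp3" = c(14.18, 12.92, 1.39),
    "O.sp2" = c(17.07, 13.79, 0.47),
    "F"     = c(14.66, 13.85, 2.31),
    "Cl"    = c(11.00, 9.69, 1.35),
    "Br"    = c(10.08, 8.47, 1.16),
    "I"     = c(9.90, 7.96, 0.96),
    "S.sp3" = c(10.14, 9.13, 1.38),
    "S.sp2" = c(10.14, 9.13, 1.38),
    "P.sp3" = c(8.90, 8.24, 0.96),
    "P.sp2" = c(8.90, 8.24, 0.96)
  )
  p
}

#' Atom-contribution logP coefficient table
#'
#' Crippen-style additive table: one contribution per atom type assigned by
#' [compute_logp()]. Values are a condensed adaptation of published
#' atom-contribution schemes; the table is an editable CSV so alternative
#' published coefficient sets can be substituted.
#' @return data.frame with columns `type`, `contribution`.
#' @export
crippen_table <- function() config_csv("crippen_logp.csv")

#' Topological PSA fragment contributions
#' @return data.frame with columns `key`, `contribution` (Angstrom squared).
#' @export
tpsa_table <- function() config_csv("tpsa_fragments.csv")

#' Linear solubility model coefficients
#'
#' Terms of the logS surrogate `logS = c0 + c1*AlogP + c2*MW + c3*N_rot +
#' c4*N_aromatic`. Editable CSV (ESOL-flavoured defaults).
#' @return data.frame with columns `term`, `coefficient`.
#' @export
logs_coefficients <- function() config_csv("logs_coefficients.csv")

#' Ionizable-group pKa table for the logD surrogate
#' @return data.frame with columns `group`, `kind` (acid/base), `pka`.
#' @export
pka_table <- function() config_csv("pka_groups.csv")

#' Salt and solvent fragment lists used by curation
#'
#' SMILES of common counter-ions and solvents whose fragments are stripped in
#' curation steps 2 and 4. Editable JSON.
#' @return character vector of SMILES.
#' @export
salt_fragments <- function() unlist(config_json("salts.json"))

#' @rdname salt_fragments
#' @export
solvent_fragments <- function() unlist(config_json("solvents.json"))

elements_allowed <- function() c("C", "H", "O", "N", "P", "S", "F", "Cl", "Br", "I")
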