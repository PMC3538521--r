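# Reactive functional-group flagging.
#
# The twelve reactive groups of the curation protocol are encoded as small
# graph patterns (atom constraints + bonds) matched by a backtracking
# subgraph matcher. The encodings are this package's own reconstruction of
# the named groups and can be edited below.

pattern_atom <- function(elem, arom = NULL, min_h = 0L, max_h = NA_integer_,
                         charge = NA_integer_, degree = NA_integer_, sp3 = NA) {
  list(elem = elem, arom = arom, min_h = min_h, max_h = max_h,
       charge = charge, degree = degree, sp3 = sp3)
}

#' Reactive-group pattern definitions
#'
#' Each pattern is a list with `name`, `atoms` (constraint list per pattern
#' atom) and `bonds` (matrix-like list of `c(i, j, order)` with order 0
#' meaning "any single/double/triple non-aromatic"). Patterns are matched as
#' subgraphs; extra bonds on matched atoms are allowed.
#' @return named list of pattern definitions.
#' @export
reactive_patterns <- function() {
  X <- c("Cl", "Br", "I")
  list(
    aldehyde = list(
      atoms = list(pattern_atom("C", arom = FALSE, min_h = 1L), pattern_atom("O")),
      bonds = list(c(1, 2, 2))),
    `alkyl-halide` = list(
      atoms = list(pattern_atom("C", arom = FALSE, sp3 = TRUE), pattern_atom(X)),
      bonds = list(c(1, 2, 1))),
    anhydride = list(
      atoms = list(pattern_atom("C", arom = FALSE), pattern_atom("O"),
                   pattern_atom("O", arom = FALSE), pattern_atom("C", arom = FALSE),
                   pattern_atom("O")),
      bonds = list(c(1, 2, 2), c(1, 3, 1), c(3, 4, 1), c(4, 5, 2))),
    diazo = list(
      atoms = list(pattern_atom("N", arom = FALSE), pattern_atom("N", arom = FALSE)),
      bonds = list(c(1, 2, 2))),
    dicarbonyl = list(
      atoms = list(pattern_atom("C", arom = FALSE), pattern_atom("O"),
                   pattern_atom("C", arom = FALSE), pattern_atom("O")),
      bonds = list(c(1, 2, 2), c(1, 3, 1), c(3, 4, 2))),
    disulfide = list(
      atoms = list(pattern_atom("S", arom = FALSE), pattern_atom("S", arom = FALSE)),
      bonds = list(c(1, 2, 1))),
    `hydrazine-N-NH2` = list(
      atoms = list(pattern_atom("N", arom = FALSE, charge = 0L),
                   pattern_atom("N", arom = FALSE, min_h = 2L, charge = 0L)),
      bonds = list(c(1, 2, 1))),
    isocyanate = list(
      atoms = list(pattern_atom("N", arom = FALSE), pattern_atom("C", arom = FALSE),
                   pattern_atom("O")),
      bonds = list(c(1, 2, 2), c(2, 3, 2))),
    isothiocyanate = list(
      atoms = list(pattern_atom("N", arom = FALSE), pattern_atom("C", arom = FALSE),
                   pattern_atom("S")),
      bonds = list(c(1, 2, 2), c(2, 3, 2))),
    peroxide = list(
      atoms = list(pattern_atom("O", arom = FALSE), pattern_atom("O", arom = FALSE)),
      bonds = list(c(1, 2, 1))),
    quaternaryamine = list(
      atoms = list(pattern_atom("N", charge = 1L, degree = 4L, max_h = 0L)),
      bonds = list()),
    `acyl-halide` = list(
      atoms = list(pattern_atom("C", arom = FALSE), pattern_atom("O"),
                   pattern_atom(c("F", X))),
      bonds = list(c(1, 2, 2), c(1, 3, 1)))
  )
}

atom_matches <- function(mol, i, spec, deg, sp3mask) {
  if (!mol$element[i] %in% spec$elem) return(FALSE)
  if (!is.null(spec$arom) && mol$aromatic[i] != spec$arom) return(FALSE)
  if (mol$nH[i] < spec$min_h) return(FALSE)
  if (!is.na(spec$max_h) && mol$nH[i] > spec$max_h) return(FALSE)
  if (!is.na(spec$charge) && mol$charge[i] != spec$charge) return(FALSE)
  if (!is.na(spec$degree) && deg[i] != spec$degree) return(FALSE)
  if (!is.na(spec$sp3) && sp3mask[i] != spec$sp3) return(FALSE)
  TRUE
}

# does `pattern` occur as a subgraph of `mol`?
match_pattern <- function(mol, pattern) {
  np <- length(pattern$atoms)
  n <- n_atoms(mol)
  if (np > n) return(FALSE)
  deg <- heavy_degree(mol)
  sp3mask <- !mol$aromatic & !atom_has_multiple_bond(mol)
  bond_lookup <- new.env(parent = emptyenv())
  for (k in seq_len(n_bonds(mol))) {
    key <- paste(min(mol$bond_from[k], mol$bond_to[k]),
                 max(mol$bond_from[k], mol$bond_to[k]))
    assign(key, k, envir = bond_lookup)
  }
  get_bond <- function(i, j) {
    key <- paste(min(i, j), max(i, j))
    if (exists(key, envir = bond_lookup)) get(key, envir = bond_lookup) else NA_integer_
  }
  bond_ok <- function(k, order) {
    if (mol$bond_aromatic[k]) return(FALSE)
    order == 0 || mol$bond_order[k] == order
  }
  cand <- lapply(pattern$atoms, function(spec)
    which(vapply(seq_len(n), atom_matches, logical(1), mol = mol, spec = spec,
                 deg = deg, sp3mask = sp3mask)))
  if (any(lengths(cand) == 0L)) return(FALSE)

  assign_next <- function(mapping) {
    p <- length(mapping) + 1L
    if (p > np) return(TRUE)
    # bonds from pattern atom p to already-mapped atoms
    req <- Filter(function(b) (b[1] == p && b[2] < p) || (b[2] == p && b[1] < p),
                  pattern$bonds)
    for (a in cand[[p]]) {
      if (a %in% mapping) next
      ok <- TRUE
      for (b in req) {
        other <- mapping[if (b[1] == p) b[2] else b[1]]
        k <- get_bond(a, other)
        if (is.na(k) || !bond_ok(k, b[3])) { ok <- FALSE; break }
      }
      if (ok && assign_next(c(mapping, a))) return(TRUE)
    }
    FALSE
  }
  assign_next(integer())
}

#' Flag reactive functional groups
#'
#' Matches a molecule against the twelve reactive-group patterns
#' ([reactive_patterns()]): aldehyde, alkyl-halide, anhydride, diazo,
#' dicarbonyl, disulfide, hydrazine-N-NH2, isocyanate, isothiocyanate,
#' peroxide, quaternary amine and acyl-halide.
#' @param mol a [molgraph()].
#' @param patterns pattern list (default [reactive_patterns()]).
#' @return list with `reactive` (logical) and `groups` (matched names).
#' @export
flag_reactive <- function(mol, patterns = reactive_patterns()) {
  if (!length(patterns) || is.null(names(patterns)))
    stop("malformed reactive pattern configuration")
  hits <- character()
  for (nm in names(patterns)) {
    pat <- patterns[[nm]]
    if (is.null(pat$atoms)) stop("malformed reactive pattern: ", nm)
    if (match_pattern(mol, pat)) hits <- c(hits, nm)
  }
  list(reactive = length(hits) > 0L, groups = hits)
}
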