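# The 44-descriptor panel plus 16 ratio descriptors.
#
# All descriptors are computed from the 2D hydrogen-suppressed graph. The
# definitions are reconstructions from their standard names: commercial
# implementations are not reproduced numerically, and logD7.4/logS are
# declared surrogates with editable coefficient tables.

DESCRIPTOR_NAMES_44 <- c(
  "AlogP", "logD7.4", "logS", "MW", "N_HBA", "N_HBD", "N_rot", "PSA",
  "N_HBAL", "N_HBDL", "MSA", "N_C", "N_N", "N_O", "N_Halogen", "N_Atom",
  "N_Bonds", "N_positive", "N_negative", "N_Spiro", "N_BHA", "N_Ringb",
  "N_aromatic", "N_Bridge", "N_Rings", "N_AR", "N_RA", "N_R3", "N_R4",
  "N_R5", "N_R6", "N_R7", "N_R8", "N_R9+", "N_Chains", "N_ChainA",
  "N_Stereo", "N_StereoB", "SC0", "SC1", "SC2", "SC3P", "SC3C", "SC3CH")

DESCRIPTOR_NAMES_16 <- c(
  "f_rot", "f_PSA", "FASA+", "FASA-", "FASA_H", "FASA_P", "FCASA+", "FCASA-",
  "FVSA+", "FVSA-", "FVSA_H", "FVSA_P", "FCVSA+", "FCVSA-", "C3P", "UNC_C3")

#' Names of the descriptor panel
#'
#' The 44 base descriptors plus the 16 size-independent ratio descriptors, in
#' canonical order.
#' @param which `"all"`, `"base"` (44) or `"ratio"` (16).
#' @return character vector.
#' @export
descriptor_names <- function(which = c("all", "base", "ratio")) {
  which <- match.arg(which)
  switch(which, base = DESCRIPTOR_NAMES_44, ratio = DESCRIPTOR_NAMES_16,
         all = c(DESCRIPTOR_NAMES_44, DESCRIPTOR_NAMES_16))
}

# per-atom helpers -----------------------------------------------------------

atom_has_multiple_bond <- function(mol) {
  res <- logical(n_atoms(mol))
  mult <- which(mol$bond_order >= 2L & !mol$bond_aromatic)
  res[c(mol$bond_from[mult], mol$bond_to[mult])] <- TRUE
  res
}

is_sp3_carbon <- function(mol) {
  mol$element == "C" & !mol$aromatic & !atom_has_multiple_bond(mol)
}

is_unsaturated_carbon <- function(mol) {
  mol$element == "C" & (mol$aromatic | atom_has_multiple_bond(mol))
}

# neighbour element list per atom
neighbour_elements <- function(mol) {
  adj <- adjacency_list(mol)
  lapply(adj, function(nb) mol$element[nb])
}

# operations ------------------------------------------------------------------

#' Elemental composition and charge counts
#'
#' Heavy-atom counts: `N_Atom` and `N_Bonds` exclude hydrogens; `MW` includes
#' hydrogens (average atomic masses); `N_positive`/`N_negative` count atoms
#' with positive/negative formal charge.
#' @param mol a [molgraph()].
#' @return named numeric vector.
#' @export
count_composition <- function(mol) {
  c(MW = molecular_weight(mol),
    N_C = sum(mol$element == "C"),
    N_N = sum(mol$element == "N"),
    N_O = sum(mol$element == "O"),
    N_Halogen = sum(mol$element %in% c("F", "Cl", "Br", "I")),
    N_Atom = n_atoms(mol),
    N_Bonds = n_bonds(mol),
    N_positive = sum(mol$charge > 0L),
    N_negative = sum(mol$charge < 0L))
}

#' Hydrogen-bond donor and acceptor counts
#'
#' Lipinski variants: `N_HBDL` is the total number of hydrogens on nitrogen
#' and oxygen; `N_HBAL` is the number of nitrogen plus oxygen atoms. Generic
#' variants: `N_HBD` counts N/O atoms bearing at least one hydrogen; `N_HBA`
#' counts N/O atoms with an available lone pair, excluding pyrrole-type
#' aromatic nitrogens (three connections), amide nitrogens and positively
#' charged nitrogens.
#' @param mol a [molgraph()].
#' @return named numeric vector with `N_HBD`, `N_HBA`, `N_HBDL`, `N_HBAL`.
#' @export
count_hbonds <- function(mol) {
  is_no <- mol$element %in% c("N", "O")
  hbdl <- sum(mol$nH[is_no])
  hbal <- sum(is_no)
  hbd <- sum(is_no & mol$nH >= 1L)
  deg <- heavy_degree(mol)
  amide_n <- amide_nitrogen_mask(mol)
  acceptor <- is_no & mol$charge <= 0L &
    !(mol$element == "N" & mol$aromatic & (deg + mol$nH) >= 3L) &
    !(mol$element == "N" & amide_n)
  c(N_HBD = hbd, N_HBA = sum(acceptor), N_HBDL = hbdl, N_HBAL = hbal)
}

# nitrogens single-bonded to a carbonyl / thiocarbonyl carbon
amide_nitrogen_mask <- function(mol) {
  res <- logical(n_atoms(mol))
  carbonyl_c <- logical(n_atoms(mol))
  for (k in seq_len(n_bonds(mol))) {
    if (mol$bond_order[k] == 2L && !mol$bond_aromatic[k]) {
      i <- mol$bond_from[k]; j <- mol$bond_to[k]
      if (mol$element[i] == "C" && mol$element[j] %in% c("O", "S")) carbonyl_c[i] <- TRUE
      if (mol$element[j] == "C" && mol$element[i] %in% c("O", "S")) carbonyl_c[j] <- TRUE
    }
  }
  for (k in seq_len(n_bonds(mol))) {
    if (mol$bond_order[k] == 1L && !mol$bond_aromatic[k]) {
      i <- mol$bond_from[k]; j <- mol$bond_to[k]
      if (mol$element[i] == "N" && carbonyl_c[j]) res[i] <- TRUE
      if (mol$element[j] == "N" && carbonyl_c[i]) res[j] <- TRUE
    }
  }
  res
}

#' Rotatable bond count
#'
#' Single, non-ring, non-aromatic bonds between two non-terminal heavy atoms,
#' excluding amide C-N bonds.
#' @param mol a [molgraph()].
#' @param rings optional precomputed [perceive_rings()] result.
#' @return integer count `N_rot`.
#' @export
count_rotatable <- function(mol, rings = NULL) {
  if (!n_bonds(mol)) return(c(N_rot = 0))
  inring <- if (is.null(rings)) ring_bond_mask(mol) else rings$bond_in_ring
  deg <- heavy_degree(mol)
  amide_n <- amide_nitrogen_mask(mol)
  carbonyl_c <- logical(n_atoms(mol))
  for (k in seq_len(n_bonds(mol))) {
    if (mol$bond_order[k] == 2L && !mol$bond_aromatic[k]) {
      i <- mol$bond_from[k]; j <- mol$bond_to[k]
      if (mol$element[i] == "C" && mol$element[j] == "O") carbonyl_c[i] <- TRUE
      if (mol$element[j] == "C" && mol$element[i] == "O") carbonyl_c[j] <- TRUE
    }
  }
  n_rot <- 0L
  for (k in seq_len(n_bonds(mol))) {
    if (mol$bond_order[k] != 1L || mol$bond_aromatic[k] || inring[k]) next
    i <- mol$bond_from[k]; j <- mol$bond_to[k]
    if (deg[i] < 2L || deg[j] < 2L) next
    amide <- (mol$element[i] == "N" && carbonyl_c[j]) ||
      (mol$element[j] == "N" && carbonyl_c[i])
    if (amide) next
    n_rot <- n_rot + 1L
  }
  c(N_rot = n_rot)
}

#' Ring-system descriptors
#'
#' Counts over the SSSR: total rings, aromatic rings, ring assemblies, rings
#' by size (nine-membered and larger pooled into `N_R9+`), ring bonds,
#' aromatic bonds, spiro atoms, and the bridged-system descriptors `N_Bridge`
#' (ring bonds belonging to bridged assemblies, i.e. assemblies where some
#' ring pair shares more than one bond) and `N_BHA` (atoms of bridged
#' assemblies with at least three incident ring bonds).
#' @param mol a [molgraph()].
#' @param rings a [perceive_rings()] result (computed if missing).
#' @return named numeric vector.
#' @export
ring_descriptors <- function(mol, rings = NULL) {
  if (is.null(rings)) rings <- perceive_rings(mol)
  sizes <- lengths(rings$sssr)
  bond_key <- paste(pmin(mol$bond_from, mol$bond_to), pmax(mol$bond_from, mol$bond_to))
  n_ar <- 0L
  for (rb in rings$sssr_bonds %||% list()) {
    if (all(mol$bond_aromatic[rb])) n_ar <- n_ar + 1L
  }
  bridged <- Filter(function(a) a$bridged, rings$assemblies)
  bridge_bonds <- unique(unlist(lapply(bridged, `[[`, "bonds")))
  n_bridge <- length(bridge_bonds)
  # ring-bond degree per atom
  ring_deg <- tabulate(c(mol$bond_from[rings$ring_bonds], mol$bond_to[rings$ring_bonds]),
                       nbins = n_atoms(mol))
  bha_atoms <- unique(unlist(lapply(bridged, `[[`, "atoms")))
  n_bha <- sum(ring_deg[bha_atoms] >= 3L)
  rk <- function(k) sum(sizes == k)
  c(N_Spiro = length(rings$spiro_atoms),
    N_BHA = n_bha,
    N_Ringb = length(rings$ring_bonds),
    N_aromatic = sum(mol$bond_aromatic),
    N_Bridge = n_bridge,
    N_Rings = length(rings$sssr),
    N_AR = n_ar,
    N_RA = length(rings$assemblies),
    N_R3 = rk(3), N_R4 = rk(4), N_R5 = rk(5), N_R6 = rk(6),
    N_R7 = rk(7), N_R8 = rk(8), "N_R9+" = sum(sizes >= 9))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Chain and stereo-complexity descriptors
#'
#' `N_ChainA`: heavy atoms outside all rings. `N_Chains`: atoms outside all
#' rings counting hydrogens (hydrogens are never ring members). `N_Stereo`:
#' potential tetrahedral stereocentres - sp3 carbons with four connections
#' whose substituents (hydrogen counted) fall in pairwise distinct symmetry
#' classes. `N_StereoB`: potential E/Z double bonds - non-ring, non-aromatic
#' C=C bonds whose two ends each carry two distinct substituents.
#' @param mol a [molgraph()].
#' @param rings a [perceive_rings()] result (computed if missing).
#' @return named numeric vector.
#' @export
chain_and_stereo <- function(mol, rings = NULL) {
  if (is.null(rings)) rings <- perceive_rings(mol)
  chain_atoms <- sum(!rings$atom_in_ring)
  chains <- chain_atoms + sum(mol$nH)
  cls <- symmetry_classes(mol)
  adj <- adjacency_list(mol)
  deg <- heavy_degree(mol)
  sp3c <- is_sp3_carbon(mol)
  n_stereo <- 0L
  for (i in seq_len(n_atoms(mol))) {
    if (!sp3c[i]) next
    if (deg[i] + mol$nH[i] != 4L || mol$nH[i] > 1L) next
    ncls <- cls[adj[[i]]]
    if (anyDuplicated(ncls)) next
    n_stereo <- n_stereo + 1L
  }
  n_stereob <- 0L
  for (k in seq_len(n_bonds(mol))) {
    if (mol$bond_order[k] != 2L || mol$bond_aromatic[k] || rings$bond_in_ring[k]) next
    i <- mol$bond_from[k]; j <- mol$bond_to[k]
    if (mol$element[i] != "C" || mol$element[j] != "C") next
    end_ok <- function(a, partner) {
      others <- setdiff(adj[[a]], partner)
      nsub <- length(others) + mol$nH[a]
      if (nsub != 2L || mol$nH[a] > 1L) return(FALSE)
      !anyDuplicated(cls[others])
    }
    if (end_ok(i, j) && end_ok(j, i)) n_stereob <- n_stereob + 1L
  }
  c(N_Chains = chains, N_ChainA = chain_atoms,
    N_Stereo = n_stereo, N_StereoB = n_stereob)
}

#' Kier & Hall subgraph counts
#'
#' Connected-subgraph counts of the heavy-atom graph: `SC0` atoms, `SC1`
#' bonds, `SC2` two-edge paths, `SC3P` three-edge paths, `SC3C` three-edge
#' clusters (K1,3 stars) and `SC3CH` three-edge rings (triangles).
#' @param mol a [molgraph()].
#' @return named numeric vector.
#' @export
subgraph_counts <- function(mol) {
  n <- n_atoms(mol)
  deg <- heavy_degree(mol)
  adj <- adjacency_list(mol)
  sc2 <- sum(choose(deg, 2))
  sc3c <- sum(choose(deg, 3))
  tri <- 0L
  for (k in seq_len(n_bonds(mol))) {
    i <- mol$bond_from[k]; j <- mol$bond_to[k]
    tri <- tri + length(intersect(adj[[i]], adj[[j]]))
  }
  tri <- tri / 3L
  sc3p <- 0L
  for (k in seq_len(n_bonds(mol))) {
    i <- mol$bond_from[k]; j <- mol$bond_to[k]
    sc3p <- sc3p + (deg[i] - 1L) * (deg[j] - 1L)
  }
  sc3p <- sc3p - 3L * tri
  c(SC0 = n, SC1 = n_bonds(mol), SC2 = sc2, SC3P = sc3p, SC3C = sc3c, SC3CH = tri)
}

# logP atom typing ------------------------------------------------------------

logp_atom_types <- function(mol) {
  nel <- neighbour_elements(mol)
  multi <- atom_has_multiple_bond(mol)
  # double/triple bond partners per atom
  hetero <- c("N", "O", "S", "P")
  dbl_to_het <- logical(n_atoms(mol))
  for (k in seq_len(n_bonds(mol))) {
    if (mol$bond_order[k] >= 2L && !mol$bond_aromatic[k]) {
      i <- mol$bond_from[k]; j <- mol$bond_to[k]
      if (mol$element[j] %in% hetero) dbl_to_het[i] <- TRUE
      if (mol$element[i] %in% hetero) dbl_to_het[j] <- TRUE
    }
  }
  amide_n <- amide_nitrogen_mask(mol)
  types <- character(n_atoms(mol))
  for (i in seq_len(n_atoms(mol))) {
    el <- mol$element[i]
    nb <- nel[[i]]
    types[i] <- switch(el,
      "C" = if (mol$aromatic[i]) {
        if (any(nb %in% c(hetero, "F", "Cl", "Br", "I"))) "C.ar.het" else "C.ar"
      } else if (dbl_to_het[i]) "C.carbonyl"
      else if (multi[i]) "C.unsat"
      else if (any(nb %in% hetero)) "C.sp3.het"
      else "C.sp3",
      "N" = if (mol$charge[i] > 0L) "N.pos"
      else if (mol$aromatic[i]) "N.ar"
      else if (amide_n[i]) "N.amide"
      else if (multi[i]) "N.sp2"
      else "N.amine",
      "O" = if (mol$charge[i] < 0L) "O.neg"
      else if (mol$aromatic[i]) "O.ar"
      else if (multi[i]) "O.carbonyl"
      else if (mol$nH[i] >= 1L) "O.hydroxyl"
      else "O.ether",
      "S" = if (mol$aromatic[i]) "S.ar" else "S",
      "P" = "P",
      "F" = "F", "Cl" = "Cl", "Br" = "Br", "I" = "I",
      "wildcard")
  }
  types
}

#' Atom-contribution logP
#'
#' Crippen-style additive octanol/water partition coefficient: each heavy
#' atom is assigned a type from its element, aromaticity, unsaturation and
#' neighbourhood, hydrogens are typed by their parent, and contributions from
#' [crippen_table()] are summed. Atoms that fit no type fall to a zero
#' wildcard contribution and are counted in the `wildcard_atoms` attribute.
#' @param mol a [molgraph()].
#' @return `AlogP` (named numeric scalar).
#' @export
compute_logp <- function(mol) {
  tab <- crippen_table()
  contr <- stats::setNames(tab$contribution, tab$type)
  types <- logp_atom_types(mol)
  htype <- ifelse(mol$element %in% c("N", "O", "S", "P"), "H.polar", "H.C")
  val <- sum(contr[types]) + sum(contr[htype] * mol$nH)
  res <- c(AlogP = unname(val))
  attr(res, "wildcard_atoms") <- sum(types == "wildcard")
  res
}

#' Topological polar surface area
#'
#' Ertl-style fragment contributions over nitrogen and oxygen environments
#' ([tpsa_table()]), summed per atom.
#' @param mol a [molgraph()].
#' @return `PSA` in Angstrom squared (named numeric scalar).
#' @export
compute_tpsa <- function(mol) {
  tab <- tpsa_table()
  contr <- stats::setNames(tab$contribution, tab$key)
  deg <- heavy_degree(mol)
  multi <- atom_has_multiple_bond(mol)
  n_dbl <- integer(n_atoms(mol)); n_tpl <- integer(n_atoms(mol))
  for (k in seq_len(n_bonds(mol))) {
    if (mol$bond_aromatic[k]) next
    if (mol$bond_order[k] == 2L) {
      n_dbl[mol$bond_from[k]] <- n_dbl[mol$bond_from[k]] + 1L
      n_dbl[mol$bond_to[k]] <- n_dbl[mol$bond_to[k]] + 1L
    } else if (mol$bond_order[k] == 3L) {
      n_tpl[mol$bond_from[k]] <- n_tpl[mol$bond_from[k]] + 1L
      n_tpl[mol$bond_to[k]] <- n_tpl[mol$bond_to[k]] + 1L
    }
  }
  total <- 0
  for (i in seq_len(n_atoms(mol))) {
    el <- mol$element[i]
    if (!el %in% c("N", "O")) next
    h <- mol$nH[i]; q <- mol$charge[i]
    key <- if (el == "O") {
      if (q < 0L) "O.neg"
      else if (mol$aromatic[i]) "O.ar"
      else if (n_dbl[i] >= 1L) "O.double"
      else if (h >= 1L) "O.single.H1"
      else "O.single.H0"
    } else {
      if (mol$aromatic[i]) {
        if (q > 0L) "N.ar.pos"
        else if (h >= 1L) "N.ar.H1"
        else if (deg[i] >= 3L) "N.ar.H0.deg3"
        else "N.ar.H0.deg2"
      } else if (q > 0L) paste0("N.pos.H", min(h, 3L))
      else if (n_dbl[i] >= 2L) "N.nitro"
      else if (n_tpl[i] >= 1L) "N.triple"
      else if (n_dbl[i] == 1L) paste0("N.double.H", min(h, 1L))
      else paste0("N.3single.H", min(h, 2L))
    }
    total <- total + contr[[key]]
  }
  c(PSA = total)
}

# ionizable-group detection for the logD surrogate
ionizable_groups <- function(mol) {
  adj <- adjacency_list(mol)
  groups <- character()
  carbonyl_c <- logical(n_atoms(mol))
  sulfonyl_s <- integer(n_atoms(mol))
  for (k in seq_len(n_bonds(mol))) {
    if (mol$bond_order[k] == 2L && !mol$bond_aromatic[k]) {
      i <- mol$bond_from[k]; j <- mol$bond_to[k]
      if (mol$element[i] == "C" && mol$element[j] == "O") carbonyl_c[i] <- TRUE
      if (mol$element[j] == "C" && mol$element[i] == "O") carbonyl_c[j] <- TRUE
      if (mol$element[i] == "S" && mol$element[j] == "O") sulfonyl_s[i] <- sulfonyl_s[i] + 1L
      if (mol$element[j] == "S" && mol$element[i] == "O") sulfonyl_s[j] <- sulfonyl_s[j] + 1L
    }
  }
  multi <- atom_has_multiple_bond(mol)
  amide_n <- amide_nitrogen_mask(mol)
  for (i in seq_len(n_atoms(mol))) {
    el <- mol$element[i]
    if (el == "O" && !mol$aromatic[i] && !multi[i] && (mol$nH[i] >= 1L || mol$charge[i] < 0L)) {
      parents <- adj[[i]]
      if (any(carbonyl_c[parents])) groups <- c(groups, "carboxylic_acid")
      if (any(sulfonyl_s[parents] >= 2L)) groups <- c(groups, "sulfonic_acid")
    }
    if (el == "N" && !mol$aromatic[i] && !multi[i] && !amide_n[i] && mol$charge[i] >= 0L) {
      nb <- adj[[i]]
      if (!any(mol$aromatic[nb])) groups <- c(groups, "aliphatic_amine")
    }
  }
  groups
}

#' Surrogate logD at pH 7.4 and logS
#'
#' `logD7.4 = AlogP - sum of ionization penalties`, one penalty
#' `log10(1 + 10^(7.4 - pKa))` per acidic group and
#' `log10(1 + 10^(pKa - 7.4))` per basic group recognised from the graph
#' (see [pka_table()]). `logS` is the linear model of [logs_coefficients()]
#' over AlogP, MW, rotatable bonds and aromatic bonds. Both are declared
#' surrogates for published regression models, with pluggable coefficients.
#' @param mol a [molgraph()].
#' @param parts optional named vector with precomputed `AlogP`, `MW`,
#'   `N_rot`, `N_aromatic` (computed if missing).
#' @return named numeric vector with `logD7.4` and `logS`.
#' @export
compute_logd_logs <- function(mol, parts = NULL) {
  need <- function(nm, f) if (!is.null(parts) && nm %in% names(parts)) parts[[nm]] else f
  alogp <- need("AlogP", compute_logp(mol)[["AlogP"]])
  mw <- need("MW", molecular_weight(mol))
  nrot <- need("N_rot", count_rotatable(mol)[["N_rot"]])
  narom <- need("N_aromatic", sum(mol$bond_aromatic))
  pka <- pka_table()
  penalty <- 0
  for (g in ionizable_groups(mol)) {
    row <- pka[pka$group == g, ]
    if (!nrow(row)) next
    penalty <- penalty + if (row$kind == "acid") log10(1 + 10^(7.4 - row$pka))
    else log10(1 + 10^(row$pka - 7.4))
  }
  cf <- logs_coefficients()
  co <- stats::setNames(cf$coefficient, cf$term)
  logs <- co[["intercept"]] + co[["AlogP"]] * alogp + co[["MW"]] * mw +
    co[["N_rot"]] * nrot + co[["N_aromatic"]] * narom
  c("logD7.4" = alogp - penalty, logS = logs)
}

#' Fractional surface-area descriptors
#'
#' From PEOE charges and approximate per-atom areas (hydrogens expanded):
#' `MSA` is the total water-accessible area; `FASA+`/`FASA-` are the area
#' fractions of atoms with positive/negative partial charge (atoms with zero
#' charge contribute to neither, so `FASA+ + FASA- + FASA0 = 1`); `FASA_P` is
#' the polar fraction (N, O, S, P and their hydrogens) and `FASA_H` its
#' complement; `FCASA+`/`FCASA-` are charge-weighted variants
#' (`sum(|q| * area)` by sign over the total). The `FVSA` family repeats the
#' definitions on van der Waals areas.
#' @param mol a [molgraph()].
#' @param ann optional [atom_annotations()] result.
#' @param zero_tol charges with absolute value below this are "zero".
#' @return named numeric vector of 13 descriptors.
#' @export
surface_descriptors <- function(mol, ann = NULL, zero_tol = 1e-12) {
  if (is.null(ann)) ann <- atom_annotations(mol)
  q <- ann$charge
  fam <- function(area) {
    tot <- sum(area)
    if (tot <= 0) stop("total surface area is zero; surface descriptors undefined")
    pos <- q > zero_tol; neg <- q < -zero_tol
    parent_el <- ifelse(is.na(ann$parent), ann$element, ann$element[ann$parent])
    polar <- parent_el %in% c("N", "O", "S", "P")
    wtot <- sum(abs(q) * area)
    fc_pos <- if (wtot > 0) sum(abs(q[pos]) * area[pos]) / wtot else 0
    fc_neg <- if (wtot > 0) sum(abs(q[neg]) * area[neg]) / wtot else 0
    c(total = tot,
      fpos = sum(area[pos]) / tot, fneg = sum(area[neg]) / tot,
      fpolar = sum(area[polar]) / tot,
      fcpos = fc_pos, fcneg = fc_neg)
  }
  a <- fam(ann$asa); v <- fam(ann$vsa)
  c(MSA = unname(a[["total"]]),
    "FASA+" = a[["fpos"]], "FASA-" = a[["fneg"]],
    FASA_H = 1 - a[["fpolar"]], FASA_P = a[["fpolar"]],
    "FCASA+" = a[["fcpos"]], "FCASA-" = a[["fcneg"]],
    "FVSA+" = v[["fpos"]], "FVSA-" = v[["fneg"]],
    FVSA_H = 1 - v[["fpolar"]], FVSA_P = v[["fpolar"]],
    "FCVSA+" = v[["fcpos"]], "FCVSA-" = v[["fcneg"]])
}

#' Ratio descriptors
#'
#' `f_rot = N_rot / N_Bonds`, `f_PSA = PSA / MSA`, `C3P` = sp3 carbons over
#' heavy atoms excluding halogens, `UNC_C3` = unsaturated carbons over sp3
#' carbons. A zero denominator yields 0 with the descriptor name recorded in
#' the `flags` attribute, so downstream screening can exclude it.
#' @param mol a [molgraph()].
#' @param parts named vector with `N_rot`, `N_Bonds`, `PSA`, `MSA` (computed
#'   if missing).
#' @return named numeric vector with a `flags` attribute.
#' @export
ratio_descriptors <- function(mol, parts = NULL) {
  need <- function(nm, f) if (!is.null(parts) && nm %in% names(parts)) parts[[nm]] else f
  nrot <- need("N_rot", count_rotatable(mol)[["N_rot"]])
  nbond <- n_bonds(mol)
  psa <- need("PSA", compute_tpsa(mol)[["PSA"]])
  msa <- need("MSA", surface_descriptors(mol)[["MSA"]])
  sp3 <- sum(is_sp3_carbon(mol))
  unsat <- sum(is_unsaturated_carbon(mol))
  nonhal <- n_atoms(mol) - sum(mol$element %in% c("F", "Cl", "Br", "I"))
  flags <- character()
  safe_div <- function(num, den, nm) {
    if (den == 0) { flags <<- c(flags, nm); 0 } else num / den
  }
  res <- c(f_rot = safe_div(nrot, nbond, "f_rot"),
           f_PSA = safe_div(psa, msa, "f_PSA"),
           C3P = safe_div(sp3, nonhal, "C3P"),
           UNC_C3 = safe_div(unsat, sp3, "UNC_C3"))
  attr(res, "flags") <- flags
  res
}

# descriptor-name -> computation-group map used for partial evaluation
descriptor_groups <- function() {
  list(
    composition = c("MW", "N_C", "N_N", "N_O", "N_Halogen", "N_Atom", "N_Bonds",
                    "N_positive", "N_negative"),
    hbonds = c("N_HBD", "N_HBA", "N_HBDL", "N_HBAL"),
    rotatable = "N_rot",
    rings = c("N_Spiro", "N_BHA", "N_Ringb", "N_aromatic", "N_Bridge", "N_Rings",
              "N_AR", "N_RA", "N_R3", "N_R4", "N_R5", "N_R6", "N_R7", "N_R8",
              "N_R9+"),
    chainstereo = c("N_Chains", "N_ChainA", "N_Stereo", "N_StereoB"),
    subgraph = c("SC0", "SC1", "SC2", "SC3P", "SC3C", "SC3CH"),
    logp = "AlogP",
    tpsa = "PSA",
    logdlogs = c("logD7.4", "logS"),
    surface = c("MSA", "FASA+", "FASA-", "FASA_H", "FASA_P", "FCASA+", "FCASA-",
                "FVSA+", "FVSA-", "FVSA_H", "FVSA_P", "FCVSA+", "FCVSA-"),
    ratio = c("f_rot", "f_PSA", "C3P", "UNC_C3")
  )
}

#' Compute the full descriptor vector of a molecule
#'
#' Evaluates the 44 base descriptors and 16 ratio descriptors (or the subset
#' named in `which`, computing only what is needed). Undefined values
#' (zero denominators) are returned as 0 and named in the `flags` attribute;
#' nothing is silently `NaN`.
#' @param mol a [molgraph()] (single-fragment for meaningful values).
#' @param which optional character vector of descriptor names to compute.
#' @return named numeric vector (in canonical order) with attributes `flags`
#'   (character) and `name` (molecule name).
#' @export
compute_descriptors <- function(mol, which = NULL) {
  all_names <- descriptor_names()
  if (is.null(which)) which <- all_names
  else {
    bad <- setdiff(which, all_names)
    if (length(bad)) stop("unknown descriptor(s): ", paste(bad, collapse = ", "))
  }
  groups <- descriptor_groups()
  want <- vapply(groups, function(g) any(g %in% which), logical(1))
  # dependency closure
  if (want[["ratio"]]) want[c("rotatable", "tpsa", "surface")] <- TRUE
  if (want[["logdlogs"]]) want[c("logp", "composition", "rotatable")] <- TRUE
  need_rings <- want[["rings"]] || want[["chainstereo"]] || want[["rotatable"]]
  rings <- if (need_rings) perceive_rings(mol) else NULL

  vals <- c()
  flags <- character()
  if (want[["composition"]]) vals <- c(vals, count_composition(mol))
  if (want[["hbonds"]]) vals <- c(vals, count_hbonds(mol))
  if (want[["rotatable"]]) vals <- c(vals, count_rotatable(mol, rings))
  if (want[["rings"]]) vals <- c(vals, ring_descriptors(mol, rings))
  if (want[["chainstereo"]]) vals <- c(vals, chain_and_stereo(mol, rings))
  if (want[["subgraph"]]) vals <- c(vals, subgraph_counts(mol))
  if (want[["logp"]]) vals <- c(vals, compute_logp(mol))
  if (want[["tpsa"]]) vals <- c(vals, compute_tpsa(mol))
  if (want[["surface"]]) vals <- c(vals, surface_descriptors(mol))
  if (want[["logdlogs"]]) {
    parts <- c(vals["AlogP"], vals["MW"], vals["N_rot"],
               N_aromatic = sum(mol$bond_aromatic))
    vals <- c(vals, compute_logd_logs(mol, parts))
  }
  if (want[["ratio"]]) {
    rd <- ratio_descriptors(mol, parts = vals)
    flags <- c(flags, attr(rd, "flags"))
    vals <- c(vals, rd)
  }
  out <- vals[which[which %in% names(vals)]]
  attr(out, "flags") <- intersect(flags, which)
  attr(out, "name") <- mol$name
  out
}

#' Descriptor table for a library of molecules
#'
#' @param mols list of [molgraph()] objects.
#' @param which optional character vector of descriptor names (default all 60).
#' @param names optional molecule names (defaults to stored names, then index).
#' @return a [tibble::tibble()] with a `molecule` column, one column per
#'   descriptor (flagged-undefined values as `NA`), and a `flags` column
#'   (comma-joined names of undefined descriptors).
#' @export
compute_descriptor_table <- function(mols, which = NULL, names = NULL) {
  if (is.null(which)) which <- descriptor_names()
  rows <- lapply(mols, compute_descriptors, which = which)
  mat <- do.call(rbind, lapply(rows, function(r) {
    v <- as.numeric(r)
    fl <- attr(r, "flags")
    v[match(fl, names(r))] <- NA_real_
    v
  }))
  if (is.null(mat)) mat <- matrix(numeric(), ncol = length(which))
  colnames(mat) <- which
  nm <- names
  if (is.null(nm)) {
    nm <- vapply(mols, function(m) m$name, character(1))
    empty <- !nzchar(nm)
    nm[empty] <- paste0("mol_", seq_along(mols)[empty])
  }
  flags <- vapply(rows, function(r) paste(attr(r, "flags"), collapse = ","), character(1))
  out <- tibble::as_tibble(as.data.frame(mat, check.names = FALSE))
  tibble::add_column(out, molecule = nm, .before = 1) -> out
  out$flags <- flags
  out
}
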