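# Partial charges (PEOE / Gasteiger-Marsili) and approximate atomic surface
# areas from the 2D graph.

peoe_class <- function(ex) {
  n <- length(ex$element)
  has_triple <- logical(n); has_double <- integer(n); arom <- ex$aromatic
  for (k in seq_along(ex$bond_from)) {
    o <- ex$bond_order[k]
    if (ex$bond_aromatic[k]) next
    if (o == 3L) { has_triple[ex$bond_from[k]] <- TRUE; has_triple[ex$bond_to[k]] <- TRUE }
    if (o == 2L) {
      has_double[ex$bond_from[k]] <- has_double[ex$bond_from[k]] + 1L
      has_double[ex$bond_to[k]] <- has_double[ex$bond_to[k]] + 1L
    }
  }
  cls <- character(n)
  for (i in seq_len(n)) {
    el <- ex$element[i]
    if (el %in% c("H", "F", "Cl", "Br", "I")) { cls[i] <- el; next }
    hyb <- if (has_triple[i] || has_double[i] >= 2L) "sp"
    else if (has_double[i] == 1L || arom[i]) "sp2" else "sp3"
    if (el %in% c("S", "P") && hyb == "sp") hyb <- "sp2"
    cls[i] <- paste(el, hyb, sep = ".")
  }
  cls
}

#' Iterative PEOE (Gasteiger-Marsili) partial charges
#'
#' Partial equalisation of orbital electronegativities: per-atom
#' electronegativity is the quadratic `a + b q + c q^2`; at each iteration a
#' charge increment proportional to the electronegativity difference across
#' every bond (normalised by the donor's cation electronegativity) flows from
#' the less to the more electronegative atom, damped by `0.5^k`. Formal
#' charges seed the iteration, so total charge is conserved exactly.
#' Hydrogens are expanded and receive their own charges.
#'
#' @param mol a [molgraph()].
#' @param n_iter number of damped iterations (default 6, classical scheme).
#' @param tol early-exit tolerance on the largest per-iteration charge change.
#' @return list with `charge` (heavy atoms, in e), `h_charge` (per expanded
#'   hydrogen), `parent` (heavy-atom index of each hydrogen), and
#'   `charge_with_h` (all expanded atoms, heavy first).
#' @export
compute_peoe_charges <- function(mol, n_iter = 6L, tol = 1e-6) {
  ex <- expand_hydrogens(mol)
  n <- length(ex$element)
  pars <- peoe_parameters()
  cls <- peoe_class(ex)
  missing <- setdiff(unique(cls), names(pars))
  if (length(missing))
    stop("no PEOE electronegativity parameters for atom class(es): ",
         paste(missing, collapse = ", "))
  abc <- do.call(rbind, pars[cls])
  chi_plus <- ifelse(ex$element == "H", 20.02, rowSums(abc))

  q <- as.numeric(ex$charge)
  bf <- ex$bond_from; bt <- ex$bond_to
  damp <- 0.5
  for (k in seq_len(n_iter)) {
    chi <- abc[, 1] + abc[, 2] * q + abc[, 3] * q * q
    d <- chi[bt] - chi[bf]
    donor <- ifelse(d > 0, bf, bt)
    dq <- abs(d) / chi_plus[donor] * damp^k
    delta <- numeric(n)
    # donor becomes more positive, acceptor more negative
    acceptor <- ifelse(d > 0, bt, bf)
    for (e in seq_along(dq)) {
      delta[donor[e]] <- delta[donor[e]] + dq[e]
      delta[acceptor[e]] <- delta[acceptor[e]] - dq[e]
    }
    q <- q + delta
    if (max(abs(delta)) < tol) break
  }
  nh <- ex$n_heavy
  list(charge = q[seq_len(nh)],
       h_charge = if (n > nh) q[(nh + 1L):n] else numeric(),
       parent = ex$parent[-seq_len(nh)],
       charge_with_h = q)
}

#' Approximate per-atom surface areas from the 2D graph
#'
#' A conformation-free additive scheme: each atom is a sphere of its Bondi
#' van der Waals radius (plus a 1.4 Angstrom water-probe radius for the
#' accessible area), and every bonded neighbour removes a spherical cap
#' computed at the idealised bond length (sum of covalent radii, shortened
#' for multiple/aromatic bonds). Only fractional surface descriptors are
#' consumed downstream, which are robust to the absolute scale of such a
#' scheme. Hydrogens are expanded and have their own areas.
#'
#' @param mol a [molgraph()].
#' @param probe water probe radius in Angstrom (1.4 by default).
#' @return list with `asa`, `vsa` (heavy atoms, Angstrom squared), `h_asa`,
#'   `h_vsa`, `parent` (heavy parent of each hydrogen), plus `asa_with_h`,
#'   `vsa_with_h`.
#' @export
approximate_atom_surfaces <- function(mol, probe = 1.4) {
  ex <- expand_hydrogens(mol)
  n <- length(ex$element)
  rv <- vdw_radii(); rc <- covalent_radii()
  miss <- setdiff(unique(ex$element), names(rv))
  if (length(miss))
    stop("no van der Waals radius for element(s): ", paste(miss, collapse = ", "))
  Rv <- rv[ex$element]
  shorten <- ifelse(ex$bond_aromatic, 0.92,
                    ifelse(ex$bond_order == 2L, 0.87,
                           ifelse(ex$bond_order == 3L, 0.78, 1)))
  dist <- (rc[ex$element[ex$bond_from]] + rc[ex$element[ex$bond_to]]) * shorten

  sphere_minus_caps <- function(R) {
    area <- 4 * pi * R^2
    for (k in seq_along(ex$bond_from)) {
      i <- ex$bond_from[k]; j <- ex$bond_to[k]; d <- dist[k]
      for (side in 1:2) {
        a <- if (side == 1L) i else j
        b <- if (side == 1L) j else i
        h <- R[a] - (d^2 + R[a]^2 - R[b]^2) / (2 * d)
        h <- min(max(h, 0), 2 * R[a])
        area[a] <- area[a] - 2 * pi * R[a] * h
      }
    }
    pmax(area, 0)
  }
  vsa <- unname(sphere_minus_caps(Rv))
  asa <- unname(sphere_minus_caps(Rv + probe))
  nh <- ex$n_heavy
  list(asa = asa[seq_len(nh)], vsa = vsa[seq_len(nh)],
       h_asa = if (n > nh) asa[(nh + 1L):n] else numeric(),
       h_vsa = if (n > nh) vsa[(nh + 1L):n] else numeric(),
       parent = ex$parent[-seq_len(nh)],
       asa_with_h = asa, vsa_with_h = vsa)
}

#' Combined atom annotations for surface descriptors
#'
#' Runs [compute_peoe_charges()] and [approximate_atom_surfaces()] once and
#' aligns them on the expanded (hydrogen-explicit) atom list.
#' @param mol a [molgraph()].
#' @return list with `element`, `parent`, `charge`, `asa`, `vsa` over expanded
#'   atoms (heavy atoms first, `parent = NA` for heavy atoms).
#' @export
atom_annotations <- function(mol) {
  ex <- expand_hydrogens(mol)
  q <- compute_peoe_charges(mol)
  s <- approximate_atom_surfaces(mol)
  list(element = ex$element, parent = ex$parent,
       charge = q$charge_with_h, asa = s$asa_with_h, vsa = s$vsa_with_h,
       n_heavy = ex$n_heavy)
}
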