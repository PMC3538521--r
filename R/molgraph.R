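#' Molecular graph objects
#'
#' A `molgraph` is the 2D hydrogen-suppressed molecular graph used throughout
#' the package: heavy atoms carry an element symbol, a formal charge, an
#' implicit/explicit hydrogen count and an aromatic flag; bonds carry an
#' integer order (1, 2, 3) and an aromatic flag. Hydrogens are implicit and
#' only expanded internally (partial charges, surface areas).
#'
#' @param element character vector of element symbols.
#' @param charge integer vector of formal charges (e).
#' @param nH integer vector of attached hydrogen counts.
#' @param aromatic logical vector of atom aromaticity flags.
#' @param bond_from,bond_to integer vectors of 1-based atom indices.
#' @param bond_order integer vector of bond orders (1, 2 or 3; aromatic bonds
#'   are stored with order 1 and `bond_aromatic = TRUE`).
#' @param bond_aromatic logical vector of bond aromaticity flags.
#' @param chiral character vector of chirality tags ("", "@" or "@@"),
#'   retained only for duplicate keys.
#' @param name molecule name.
#' @return an object of class `molgraph`.
#' @export
molgraph <- function(element, charge = integer(length(element)),
                     nH = integer(length(element)),
                     aromatic = logical(length(element)),
                     bond_from = integer(), bond_to = integer(),
                     bond_order = integer(), bond_aromatic = logical(length(bond_from)),
                     chiral = character(length(element)), name = "") {
  m <- structure(list(
    element = as.character(element),
    charge = as.integer(charge),
    nH = as.integer(nH),
    aromatic = as.logical(aromatic),
    chiral = as.character(chiral),
    bond_from = as.integer(bond_from),
    bond_to = as.integer(bond_to),
    bond_order = as.integer(bond_order),
    bond_aromatic = as.logical(bond_aromatic),
    name = as.character(name)[1]
  ), class = "molgraph")
  m
}

#' @export
print.molgraph <- function(x, ...) {
  cat(sprintf("<molgraph%s: %d heavy atoms, %d bonds, %d component(s), MW %.2f>\n",
              if (nzchar(x$name)) paste0(" ", x$name) else "",
              n_atoms(x), n_bonds(x), n_components(x), molecular_weight(x)))
  invisible(x)
}

#' @rdname molgraph
#' @param x object.
#' @export
is.molgraph <- function(x) inherits(x, "molgraph")

#' Atom and bond counts of the heavy-atom graph
#' @param mol a `molgraph`.
#' @return integer count.
#' @export
n_atoms <- function(mol) length(mol$element)

#' @rdname n_atoms
#' @export
n_bonds <- function(mol) length(mol$bond_from)

# adjacency as list of integer neighbour vectors (heavy atoms only)
adjacency_list <- function(mol) {
  n <- n_atoms(mol)
  adj <- vector("list", n)
  if (n_bonds(mol)) {
    ends <- c(mol$bond_from, mol$bond_to)
    othr <- c(mol$bond_to, mol$bond_from)
    o <- order(ends)
    adj_split <- split(othr[o], ends[o])
    adj[as.integer(names(adj_split))] <- adj_split
  }
  for (i in seq_len(n)) if (is.null(adj[[i]])) adj[[i]] <- integer()
  adj
}

# per-atom incident bond indices
incident_bonds <- function(mol) {
  n <- n_atoms(mol)
  inc <- vector("list", n)
  if (n_bonds(mol)) {
    ends <- c(mol$bond_from, mol$bond_to)
    bidx <- rep(seq_len(n_bonds(mol)), 2L)
    o <- order(ends)
    sp <- split(bidx[o], ends[o])
    inc[as.integer(names(sp))] <- sp
  }
  for (i in seq_len(n)) if (is.null(inc[[i]])) inc[[i]] <- integer()
  inc
}

heavy_degree <- function(mol) {
  tabulate(c(mol$bond_from, mol$bond_to), nbins = n_atoms(mol))
}

#' Connected components of a molecular graph
#'
#' @param mol a `molgraph`.
#' @return integer vector assigning each atom a component id (1-based).
#' @export
components <- function(mol) {
  n <- n_atoms(mol)
  comp <- integer(n)
  if (n == 0L) return(comp)
  adj <- adjacency_list(mol)
  cid <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cid <- cid + 1L
    queue <- s
    comp[s] <- cid
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      nb <- adj[[v]]
      new <- nb[comp[nb] == 0L]
      comp[new] <- cid
      queue <- c(queue, new)
    }
  }
  comp
}

#' @rdname components
#' @export
n_components <- function(mol) {
  if (n_atoms(mol) == 0L) return(0L)
  max(components(mol))
}

#' Extract one connected component as a new molgraph
#' @param mol a `molgraph`.
#' @param id component id as returned by [components()].
#' @keywords internal
extract_component <- function(mol, id) {
  comp <- components(mol)
  keep_atoms(mol, which(comp == id))
}

# subset atoms (and induced bonds), remapping indices
keep_atoms <- function(mol, idx) {
  idx <- sort(unique(as.integer(idx)))
  map <- integer(n_atoms(mol))
  map[idx] <- seq_along(idx)
  bkeep <- mol$bond_from %in% idx & mol$bond_to %in% idx
  molgraph(
    element = mol$element[idx], charge = mol$charge[idx], nH = mol$nH[idx],
    aromatic = mol$aromatic[idx], chiral = mol$chiral[idx],
    bond_from = map[mol$bond_from[bkeep]], bond_to = map[mol$bond_to[bkeep]],
    bond_order = mol$bond_order[bkeep], bond_aromatic = mol$bond_aromatic[bkeep],
    name = mol$name
  )
}

# permute atom order (testing helper exported for property tests)
#' Reorder atoms of a molecule
#'
#' Returns the same molecule with atoms listed in the order `perm`. All
#' descriptors are invariant under this operation.
#' @param mol a `molgraph`.
#' @param perm a permutation of `seq_len(n_atoms(mol))`.
#' @export
permute_atoms <- function(mol, perm) {
  perm <- as.integer(perm)
  stopifnot(length(perm) == n_atoms(mol), all(sort(perm) == seq_len(n_atoms(mol))))
  inv <- integer(length(perm)); inv[perm] <- seq_along(perm)
  molgraph(
    element = mol$element[perm], charge = mol$charge[perm], nH = mol$nH[perm],
    aromatic = mol$aromatic[perm], chiral = mol$chiral[perm],
    bond_from = inv[mol$bond_from], bond_to = inv[mol$bond_to],
    bond_order = mol$bond_order, bond_aromatic = mol$bond_aromatic,
    name = mol$name
  )
}

#' Molecular weight from average atomic masses
#'
#' Includes implicit hydrogens. Average (not monoisotopic) atomic masses are
#' used throughout.
#' @param mol a `molgraph`.
#' @return molecular weight in Da.
#' @export
molecular_weight <- function(mol) {
  masses <- atomic_masses()
  m <- masses[mol$element]
  if (anyNA(m)) {
    bad <- unique(mol$element[is.na(m)])
    stop("no atomic mass for element(s): ", paste(bad, collapse = ", "))
  }
  sum(m) + sum(mol$nH) * masses[["H"]]
}

# effective valence used for validity checking; aromatic atoms are checked by
# sigma-connection count instead of summed bond order
check_valence <- function(mol) {
  n <- n_atoms(mol)
  if (n == 0L) return(TRUE)
  deg <- heavy_degree(mol)
  ordsum <- numeric(n)
  if (n_bonds(mol)) {
    ords <- ifelse(mol$bond_aromatic, 1.5, mol$bond_order)
    for (k in seq_len(n_bonds(mol))) {
      ordsum[mol$bond_from[k]] <- ordsum[mol$bond_from[k]] + ords[k]
      ordsum[mol$bond_to[k]] <- ordsum[mol$bond_to[k]] + ords[k]
    }
  }
  for (i in seq_len(n)) {
    el <- mol$element[i]; q <- mol$charge[i]
    if (mol$aromatic[i]) {
      conn <- deg[i] + mol$nH[i]
      ok <- switch(el,
        "C" = conn == 3L, "B" = conn == 3L,
        "N" = conn %in% 2:3, "P" = conn %in% 2:3,
        "O" = conn == 2L, "S" = conn %in% c(2L, 3L), TRUE)
      if (!ok) return(FALSE)
      next
    }
    v <- ordsum[i] + mol$nH[i]
    allowed <- allowed_valences(el, q)
    if (is.null(allowed)) next  # unparameterized element: curation removes it
    if (!any(abs(v - allowed) < 1e-9)) return(FALSE)
  }
  TRUE
}

allowed_valences <- function(el, q) {
  if (el == "C") return(if (q == 0L) 4 else 3)
  if (el == "N") return(if (q == 0L) c(3, 5) else if (q > 0L) 4 else 2)
  if (el == "O") return(if (q == 0L) 2 else if (q > 0L) 3 else c(0, 1))
  if (el == "S") return(if (q == 0L) c(2, 4, 6) else if (q < 0L) c(0, 1) else c(3, 5))
  if (el == "P") return(c(3, 5))
  if (el %in% c("F", "Cl", "Br", "I")) return(if (q == 0L) 1 else 0)
  if (el == "H") return(if (q == 0L) 1 else 0)
  if (el == "B") return(3)
  NULL
}

#' Expand implicit hydrogens
#'
#' Builds the all-atom graph (heavy atoms first, then one node per implicit
#' hydrogen) used by the partial-charge and surface-area routines.
#' @param mol a `molgraph`.
#' @return list with `element`, `charge`, `aromatic`, `parent` (heavy-atom
#'   index for hydrogens, NA for heavy atoms kept as themselves), `bond_from`,
#'   `bond_to`, `bond_order`, `bond_aromatic`, and `n_heavy`.
#' @keywords internal
expand_hydrogens <- function(mol) {
  nh <- n_atoms(mol)
  nHtot <- sum(mol$nH)
  element <- c(mol$element, rep("H", nHtot))
  charge <- c(mol$charge, integer(nHtot))
  aromatic <- c(mol$aromatic, logical(nHtot))
  parent <- c(rep(NA_integer_, nh), rep(seq_len(nh), mol$nH))
  h_idx <- which(parent > 0L)
  bond_from <- c(mol$bond_from, parent[h_idx])
  bond_to <- c(mol$bond_to, h_idx)
  bond_order <- c(mol$bond_order, rep(1L, nHtot))
  bond_aromatic <- c(mol$bond_aromatic, logical(nHtot))
  list(element = element, charge = charge, aromatic = aromatic,
       parent = parent, bond_from = bond_from, bond_to = bond_to,
       bond_order = bond_order, bond_aromatic = bond_aromatic, n_heavy = nh)
}

#' Graph-invariant atom symmetry classes
#'
#' Iterative neighbourhood refinement (Morgan/Weisfeiler-Lehman style) of an
#' initial invariant (element, charge, H count, aromaticity, degree). Atoms in
#' different classes are guaranteed non-equivalent; atoms in the same class
#' are treated as topologically equivalent. Used for stereocentre detection
#' and duplicate keys.
#' @param mol a `molgraph`.
#' @return integer vector of class ids.
#' @export
symmetry_classes <- function(mol) {
  n <- n_atoms(mol)
  if (n == 0L) return(integer())
  deg <- heavy_degree(mol)
  lab <- paste(mol$element, mol$charge, mol$nH, mol$aromatic, deg, sep = "|")
  cls <- match(lab, sort(unique(lab)))
  inc <- incident_bonds(mol)
  bord <- ifelse(mol$bond_aromatic, "a", as.character(mol$bond_order))
  other <- function(b, i) ifelse(mol$bond_from[b] == i, mol$bond_to[b], mol$bond_from[b])
  nclasses <- length(unique(cls))
  for (iter in seq_len(n)) {
    newlab <- character(n)
    for (i in seq_len(n)) {
      bs <- inc[[i]]
      nb <- if (length(bs)) sort(paste0(bord[bs], ":", cls[other(bs, i)])) else character()
      newlab[i] <- paste(cls[i], paste(nb, collapse = ","), sep = ";")
    }
    newcls <- match(newlab, sort(unique(newlab)))
    k <- length(unique(newcls))
    cls <- newcls
    if (k == nclasses) break
    nclasses <- k
  }
  cls
}

#' Canonical structure key for duplicate detection
#'
#' An order-invariant key built from the stable symmetry-class partition:
#' multisets of atom classes and of class-labelled bonds, plus a summary of
#' chirality tags. Two identical structures always share a key regardless of
#' input atom order; distinct structures collide only if they are
#' Weisfeiler-Lehman-indistinguishable, which does not occur for ordinary
#' organic molecules at this size.
#' @param mol a `molgraph`.
#' @return character key.
#' @export
canonical_key <- function(mol) {
  n <- n_atoms(mol)
  if (n == 0L) return("empty")
  cls <- symmetry_classes(mol)
  deg <- heavy_degree(mol)
  atom_tag <- paste(mol$element, mol$charge, mol$nH, mol$aromatic, deg, cls, sep = "|")
  bonds <- if (n_bonds(mol)) {
    a <- pmin(cls[mol$bond_from], cls[mol$bond_to])
    b <- pmax(cls[mol$bond_from], cls[mol$bond_to])
    ord <- ifelse(mol$bond_aromatic, "a", as.character(mol$bond_order))
    sort(paste(a, ord, b, sep = "-"))
  } else character()
  stereo <- sort(paste0(cls[mol$chiral != ""], mol$chiral[mol$chiral != ""]))
  paste(
    paste(sort(atom_tag), collapse = " "),
    paste(bonds, collapse = " "),
    paste(stereo, collapse = " "),
    sep = " / "
  )
}
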