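# Ring perception: smallest set of smallest rings (a minimum cycle basis),
# ring assemblies, spiro atoms and bridged systems.

#' Perceive rings of a molecular graph
#'
#' Computes an SSSR (smallest set of smallest rings, i.e. a minimum cycle
#' basis) by generating Horton candidate cycles (shortest cycle through each
#' ring bond via each ring atom) and greedily selecting linearly independent
#' cycles over GF(2) in order of increasing size. Ring assemblies are the
#' connected components of the SSSR under shared atoms: fused, bridged and
#' spiro-linked rings belong to one assembly. An assembly is *bridged* when
#' some pair of its SSSR rings shares more than one bond (e.g. norbornane);
#' a *spiro* atom is shared by two rings that have no other atom in common.
#'
#' @param mol a [molgraph()].
#' @return an object of class `ring_info`: list with `sssr` (list of ordered
#'   atom-index cycles), `ring_bonds` (bond indices in any ring), `atom_in_ring`
#'   and `bond_in_ring` logical masks, `assemblies` (list with `rings`,
#'   `atoms`, `bonds`, `bridged`), and `spiro_atoms`.
#' @export
perceive_rings <- function(mol) {
  n <- n_atoms(mol)
  nb <- n_bonds(mol)
  comp <- if (n) components(mol) else integer()
  m <- nb - n + (if (n) max(comp) else 0L)  # cyclomatic number
  empty <- structure(list(sssr = list(), ring_bonds = integer(),
                          atom_in_ring = logical(n), bond_in_ring = logical(nb),
                          assemblies = list(), spiro_atoms = integer()),
                     class = "ring_info")
  if (m <= 0L) return(empty)

  rb_mask <- ring_bond_mask(mol)
  ring_atoms <- unique(c(mol$bond_from[rb_mask], mol$bond_to[rb_mask]))
  adj <- adjacency_list(mol)

  bond_id <- function(i, j) {
    which((mol$bond_from == i & mol$bond_to == j) | (mol$bond_from == j & mol$bond_to == i))[1]
  }

  # BFS shortest path trees from each ring atom (restricted to ring bonds
  # keeps cycles tight and small)
  bfs_parent <- function(src) {
    dist <- rep(NA_integer_, n); par <- rep(NA_integer_, n)
    dist[src] <- 0L
    queue <- src
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      for (u in adj[[v]]) {
        if (is.na(dist[u])) {
          dist[u] <- dist[v] + 1L; par[u] <- v
          queue <- c(queue, u)
        }
      }
    }
    list(dist = dist, par = par)
  }
  path_to <- function(bfs, v) {
    p <- v
    while (!is.na(bfs$par[v])) { v <- bfs$par[v]; p <- c(p, v) }
    rev(p)  # from source to v
  }

  candidates <- list(); cand_keys <- character()
  rb_idx <- which(rb_mask)
  for (x in ring_atoms) {
    bfs <- bfs_parent(x)
    for (k in rb_idx) {
      u <- mol$bond_from[k]; v <- mol$bond_to[k]
      if (is.na(bfs$dist[u]) || is.na(bfs$dist[v])) next
      pu <- path_to(bfs, u); pv <- path_to(bfs, v)
      # paths must be disjoint except at x for a simple cycle
      if (length(intersect(pu[-1], pv[-1])) > 0L) next
      cycle <- c(pu, rev(pv)[-length(pv)])
      if (length(cycle) < 3L) next
      key <- paste(sort(cycle), collapse = ",")
      if (key %in% cand_keys) next
      cand_keys <- c(cand_keys, key)
      candidates[[length(candidates) + 1L]] <- cycle
    }
  }
  if (!length(candidates)) return(empty)
  candidates <- candidates[order(lengths(candidates))]

  # greedy GF(2) independence over bond incidence vectors
  cycle_bonds <- function(cyc) {
    len <- length(cyc)
    vapply(seq_len(len), function(t) bond_id(cyc[t], cyc[t %% len + 1L]), integer(1))
  }
  basis <- list()
  sssr <- list(); sssr_bonds <- list()
  for (cyc in candidates) {
    bvec <- logical(nb)
    cb <- cycle_bonds(cyc)
    if (anyNA(cb)) next
    bvec[cb] <- TRUE
    red <- bvec
    for (b in basis) {
      pivot <- which(b)[1]
      if (red[pivot]) red <- xor(red, b)
    }
    if (!any(red)) next
    basis[[length(basis) + 1L]] <- red
    sssr[[length(sssr) + 1L]] <- cyc
    sssr_bonds[[length(sssr_bonds) + 1L]] <- cb
    if (length(sssr) == m) break
  }

  ring_bonds <- sort(unique(unlist(sssr_bonds)))
  atom_in_ring <- logical(n)
  atom_in_ring[unique(unlist(sssr))] <- TRUE
  bond_in_ring <- logical(nb)
  bond_in_ring[ring_bonds] <- TRUE

  # assemblies: components of the ring-overlap graph (shared atom => linked)
  nr <- length(sssr)
  ring_comp <- seq_len(nr)
  if (nr > 1L) {
    for (i in seq_len(nr - 1L)) for (j in (i + 1L):nr) {
      if (length(intersect(sssr[[i]], sssr[[j]]))) {
        old <- ring_comp[j]; new <- ring_comp[i]
        ring_comp[ring_comp == old] <- new
      }
    }
  }
  assemblies <- lapply(unique(ring_comp), function(cid) {
    rs <- which(ring_comp == cid)
    bridged <- FALSE
    if (length(rs) > 1L) {
      for (a in seq_along(rs)) for (b in seq_along(rs)) {
        if (a < b && length(intersect(sssr_bonds[[rs[a]]], sssr_bonds[[rs[b]]])) > 1L)
          bridged <- TRUE
      }
    }
    list(rings = rs,
         atoms = sort(unique(unlist(sssr[rs]))),
         bonds = sort(unique(unlist(sssr_bonds[rs]))),
         bridged = bridged)
  })

  spiro <- integer()
  if (nr > 1L) {
    for (i in seq_len(nr - 1L)) for (j in (i + 1L):nr) {
      shared <- intersect(sssr[[i]], sssr[[j]])
      if (length(shared) == 1L) spiro <- c(spiro, shared)
    }
  }

  structure(list(sssr = sssr, sssr_bonds = sssr_bonds, ring_bonds = ring_bonds,
                 atom_in_ring = atom_in_ring, bond_in_ring = bond_in_ring,
                 assemblies = assemblies, spiro_atoms = sort(unique(spiro))),
            class = "ring_info")
}

#' @export
print.ring_info <- function(x, ...) {
  cat(sprintf("<ring_info: %d SSSR ring(s), %d assembly(ies), %d spiro atom(s)>\n",
              length(x$sssr), length(x$assemblies), length(x$spiro_atoms)))
  invisible(x)
}
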