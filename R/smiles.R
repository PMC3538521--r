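# SMILES parsing and writing.
#
# The parser covers the organic subset, bracket atoms with charges and
# explicit H counts, branches, ring closures (including %nn), aromatic
# lowercase atoms, and '.'-separated multi-component records. Chirality
# marks (@/@@) are recorded so duplicate keys can be stereo-aware, but no
# 3D interpretation is attempted; directional bond marks (/ and \) are
# accepted and treated as single bonds.

ORGANIC_SUBSET <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")
AROMATIC_ELEMENTS <- c("b", "c", "n", "o", "p", "s", "se", "as")
KNOWN_ELEMENTS <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne", "Na", "Mg", "Al",
  "Si", "P", "S", "Cl", "Ar", "K", "Ca", "Ti", "V", "Cr", "Mn", "Fe", "Co",
  "Ni", "Cu", "Zn", "Ga", "Ge", "As", "Se", "Br", "Kr", "Rb", "Sr", "Zr",
  "Mo", "Ru", "Rh", "Pd", "Ag", "Cd", "In", "Sn", "Sb", "Te", "I", "Xe",
  "Cs", "Ba", "W", "Re", "Os", "Ir", "Pt", "Au", "Hg", "Tl", "Pb", "Bi")

parse_error <- function(smiles, reason) {
  stop(structure(class = c("druglike_parse_error", "error", "condition"),
                 list(message = sprintf("cannot parse %s: %s", dQuote(smiles), reason),
                      call = NULL, smiles = smiles, reason = reason)))
}

#' Parse a SMILES string into a molecular graph
#'
#' Aromaticity is taken from lowercase input atoms and additionally perceived
#' on kekulized input with a Hueckel-style rule over SSSR rings (all ring
#' atoms pi-capable and 4n+2 pi electrons). Implicit hydrogen counts are
#' assigned from default valences. Multi-fragment records ('.'-separated)
#' yield a multi-component graph; splitting is left to curation.
#'
#' @param smiles a single SMILES string.
#' @param name optional molecule name.
#' @param check if `TRUE` (default) reject graphs with impossible valences.
#' @return a [molgraph()].
#' @export
parse_smiles <- function(smiles, name = "", check = TRUE) {
  if (!is.character(smiles) || length(smiles) != 1L || !nzchar(trimws(smiles)))
    parse_error(smiles, "empty input")
  s <- trimws(smiles)
  chars <- strsplit(s, "")[[1]]
  n_max <- length(chars)

  element <- character(); charge <- integer(); nH <- integer()
  aromatic <- logical(); chiral <- character(); explicitH <- logical()
  bf <- integer(); bt <- integer(); bo <- integer(); ba <- logical()

  prev <- NA_integer_
  stack <- integer()
  pending <- ""          # pending bond symbol
  ring_open <- list()    # digit -> list(atom, sym)

  add_atom <- function(el, q, h, arom, chir, hexp) {
    element[[length(element) + 1L]] <<- el
    charge[[length(charge) + 1L]] <<- q
    nH[[length(nH) + 1L]] <<- h
    aromatic[[length(aromatic) + 1L]] <<- arom
    chiral[[length(chiral) + 1L]] <<- chir
    explicitH[[length(explicitH) + 1L]] <<- hexp
    idx <- length(element)
    if (!is.na(prev)) add_bond(prev, idx, pending)
    pending <<- ""
    prev <<- idx
    idx
  }
  add_bond <- function(i, j, sym) {
    if (i == j) parse_error(s, "self bond")
    if (any((bf == i & bt == j) | (bf == j & bt == i)))
      parse_error(s, "parallel bond")
    arom <- FALSE; ord <- 1L
    if (sym == "=") ord <- 2L
    else if (sym == "#") ord <- 3L
    else if (sym == ":") arom <- TRUE
    else if (sym %in% c("", "/", "\\")) {
      if (sym == "" && aromatic[i] && aromatic[j]) arom <- TRUE
    } else if (sym != "-") parse_error(s, paste0("bad bond symbol ", sym))
    bf[[length(bf) + 1L]] <<- i; bt[[length(bt) + 1L]] <<- j
    bo[[length(bo) + 1L]] <<- ord; ba[[length(ba) + 1L]] <<- arom
  }
  close_ring <- function(d) {
    if (is.na(prev)) parse_error(s, "ring closure before any atom")
    if (!is.null(ring_open[[d]])) {
      op <- ring_open[[d]]
      sym <- if (nzchar(pending)) pending else op$sym
      if (nzchar(op$sym) && nzchar(pending) && op$sym != pending)
        parse_error(s, "conflicting ring-closure bond symbols")
      saved <- pending; pending <<- sym
      add_bond(op$atom, prev, pending)
      pending <<- ""
      ring_open[[d]] <<- NULL
    } else {
      ring_open[[d]] <<- list(atom = prev, sym = pending)
      pending <<- ""
    }
  }

  i <- 1L
  while (i <= n_max) {
    ch <- chars[i]
    two <- if (i < n_max) paste0(ch, chars[i + 1L]) else ""
    if (ch == "[") {
      j <- i
      while (j <= n_max && chars[j] != "]") j <- j + 1L
      if (j > n_max) parse_error(s, "unclosed bracket")
      body <- substr(s, i + 1L, j - 1L)
      m <- regmatches(body, regexec(
        "^([0-9]*)([A-Za-z][a-z]?|\\*)(@{1,2}|@TH[12])?(H[0-9]*)?(\\+{1,3}|-{1,3}|\\+[0-9]+|-[0-9]+)?(:[0-9]+)?$",
        body))[[1]]
      if (length(m) == 0L) parse_error(s, paste0("bad bracket atom [", body, "]"))
      sym <- m[3]
      arom <- sym %in% AROMATIC_ELEMENTS
      el <- if (arom) paste0(toupper(substr(sym, 1, 1)), substr(sym, 2, 10)) else sym
      if (!el %in% KNOWN_ELEMENTS)
        parse_error(s, paste0("unknown element [", sym, "]"))
      chir <- if (nzchar(m[4])) (if (m[4] %in% c("@", "@TH1")) "@" else "@@") else ""
      h <- if (!nzchar(m[5])) 0L else if (m[5] == "H") 1L else as.integer(substr(m[5], 2, 10))
      q <- 0L
      if (nzchar(m[6])) {
        qs <- m[6]
        q <- if (qs %in% c("+", "++", "+++")) nchar(qs)
        else if (qs %in% c("-", "--", "---")) -nchar(qs)
        else as.integer(qs)
      }
      add_atom(el, as.integer(q), h, arom, chir, TRUE)
      i <- j + 1L
    } else if (two %in% c("Cl", "Br")) {
      add_atom(two, 0L, 0L, FALSE, "", FALSE); i <- i + 2L
    } else if (ch %in% c("B", "C", "N", "O", "P", "S", "F", "I")) {
      add_atom(ch, 0L, 0L, FALSE, "", FALSE); i <- i + 1L
    } else if (ch %in% c("b", "c", "n", "o", "p", "s")) {
      add_atom(toupper(ch), 0L, 0L, TRUE, "", FALSE); i <- i + 1L
    } else if (ch %in% c("-", "=", "#", ":", "/", "\\")) {
      pending <- ch; i <- i + 1L
    } else if (ch == "(") {
      if (is.na(prev)) parse_error(s, "branch before any atom")
      stack <- c(stack, prev); i <- i + 1L
    } else if (ch == ")") {
      if (!length(stack)) parse_error(s, "unbalanced parentheses")
      prev <- stack[length(stack)]; stack <- stack[-length(stack)]
      i <- i + 1L
    } else if (ch == ".") {
      prev <- NA_integer_; pending <- ""; i <- i + 1L
    } else if (grepl("^[0-9]$", ch)) {
      close_ring(ch); i <- i + 1L
    } else if (ch == "%") {
      if (i + 2L > n_max) parse_error(s, "bad %nn ring closure")
      close_ring(substr(s, i + 1L, i + 2L)); i <- i + 3L
    } else if (ch %in% c(" ", "\t")) {
      break  # trailing name field handled by read_library
    } else parse_error(s, paste0("unexpected character ", dQuote(ch)))
  }
  if (length(stack)) parse_error(s, "unbalanced parentheses")
  if (length(ring_open)) {
    open <- !vapply(ring_open, is.null, logical(1))
    if (any(open)) parse_error(s, "unclosed ring bond")
  }
  if (!length(element)) parse_error(s, "no atoms")

  mol <- molgraph(element, charge, nH, aromatic, bf, bt, bo, ba, chiral, name)
  mol <- finalize_molgraph(mol, explicitH)
  if (check && !check_valence(mol)) parse_error(s, "valence violation")
  mol
}

# post-parse normalisation: fold explicit H atoms, demote non-ring "aromatic"
# bonds, assign implicit hydrogens, Hueckel-perceive kekulized rings
finalize_molgraph <- function(mol, explicitH) {
  # fold explicit [H] atoms into the neighbour's H count
  h_atoms <- which(mol$element == "H" & mol$charge == 0L)
  if (length(h_atoms)) {
    inc <- incident_bonds(mol)
    fold <- h_atoms[vapply(h_atoms, function(i) {
      bs <- inc[[i]]
      length(bs) == 1L && mol$bond_order[bs] == 1L && !mol$bond_aromatic[bs]
    }, logical(1))]
    if (length(fold)) {
      for (i in fold) {
        b <- inc[[i]][1]
        j <- if (mol$bond_from[b] == i) mol$bond_to[b] else mol$bond_from[b]
        if (!(j %in% fold)) mol$nH[j] <- mol$nH[j] + 1L else fold <- setdiff(fold, i)
      }
      keep <- setdiff(seq_len(n_atoms(mol)), fold)
      expl <- explicitH[keep]
      mol <- keep_atoms(mol, keep)
      explicitH <- expl
    }
  }

  ring_b <- ring_bond_mask(mol)
  demote <- mol$bond_aromatic & !ring_b
  if (any(demote)) {
    mol$bond_aromatic[demote] <- FALSE
    mol$bond_order[demote] <- 1L
  }
  # atoms flagged aromatic with no aromatic ring bond are demoted
  has_arom_bond <- logical(n_atoms(mol))
  ab <- which(mol$bond_aromatic)
  has_arom_bond[c(mol$bond_from[ab], mol$bond_to[ab])] <- TRUE
  mol$aromatic <- mol$aromatic & has_arom_bond

  # implicit hydrogens for organic-subset atoms (bracket atoms are explicit)
  need <- !explicitH
  if (any(need)) mol$nH[need] <- infer_implicit_h(mol)[need]

  perceive_aromaticity(mol)
}

infer_implicit_h <- function(mol) {
  n <- n_atoms(mol)
  ordsum <- numeric(n)
  if (n_bonds(mol)) {
    ords <- ifelse(mol$bond_aromatic, 1.5, mol$bond_order)
    for (k in seq_len(n_bonds(mol))) {
      ordsum[mol$bond_from[k]] <- ordsum[mol$bond_from[k]] + ords[k]
      ordsum[mol$bond_to[k]] <- ordsum[mol$bond_to[k]] + ords[k]
    }
  }
  h <- integer(n)
  for (i in seq_len(n)) {
    el <- mol$element[i]
    if (!el %in% c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")) next
    allowed <- allowed_valences(el, mol$charge[i])
    if (is.null(allowed)) next
    v <- ceiling(ordsum[i] - 1e-9)
    target <- allowed[allowed >= v][1]
    if (is.na(target)) target <- max(allowed)
    h[i] <- max(0L, as.integer(target - v))
  }
  h
}

# bond-is-in-a-ring mask: a bond is a ring bond iff it is not a bridge
ring_bond_mask <- function(mol) {
  nb <- n_bonds(mol)
  if (!nb) return(logical())
  !vapply(seq_len(nb), function(k) is_bridge(mol, k), logical(1))
}

is_bridge <- function(mol, k) {
  a <- mol$bond_from[k]; b <- mol$bond_to[k]
  n <- n_atoms(mol)
  seen <- logical(n); seen[a] <- TRUE
  queue <- a
  adj <- adjacency_pairs(mol, exclude = k)
  while (length(queue)) {
    v <- queue[[1]]; queue <- queue[-1]
    nb <- adj[[v]]
    nb <- nb[!seen[nb]]
    if (b %in% nb) return(FALSE)
    seen[nb] <- TRUE
    queue <- c(queue, nb)
  }
  TRUE
}

adjacency_pairs <- function(mol, exclude = integer()) {
  n <- n_atoms(mol)
  adj <- vector("list", n)
  for (i in seq_len(n)) adj[[i]] <- integer()
  for (k in seq_len(n_bonds(mol))) {
    if (k %in% exclude) next
    adj[[mol$bond_from[k]]] <- c(adj[[mol$bond_from[k]]], mol$bond_to[k])
    adj[[mol$bond_to[k]]] <- c(adj[[mol$bond_to[k]]], mol$bond_from[k])
  }
  adj
}

# Hueckel-style aromaticity perception over SSSR rings of kekulized input.
# An atom is pi-capable if it is already aromatic, carries an in-ring double
# bond (1 electron), has an exocyclic multiple bond (0 electrons), or is a
# heteroatom (N, O, S) with a lone pair (2 electrons). Saturated carbons are
# not capable. Rings where all atoms are capable and the electron count is
# 4n+2 are flagged aromatic; a few passes catch fused dependencies.
perceive_aromaticity <- function(mol) {
  if (!n_bonds(mol)) return(mol)
  ri <- perceive_rings(mol)
  if (!length(ri$sssr)) return(mol)
  bond_key <- function(i, j) paste(pmin(i, j), pmax(i, j))
  bkeys <- bond_key(mol$bond_from, mol$bond_to)
  for (pass in 1:4) {
    changed <- FALSE
    for (ring in ri$sssr) {
      m <- length(ring)
      rb <- match(bond_key(ring, ring[c(2:m, 1)]), bkeys)
      if (all(mol$bond_aromatic[rb])) next
      pi_e <- 0; ok <- TRUE
      for (a in ring) {
        inc <- which(mol$bond_from == a | mol$bond_to == a)
        dbl <- inc[mol$bond_order[inc] >= 2L & !mol$bond_aromatic[inc]]
        other <- ifelse(mol$bond_from[dbl] == a, mol$bond_to[dbl], mol$bond_from[dbl])
        if (mol$aromatic[a]) pi_e <- pi_e + 1
        else if (any(other %in% ring)) pi_e <- pi_e + 1
        else if (length(dbl)) pi_e <- pi_e + 0   # exocyclic multiple bond
        else if (mol$element[a] %in% c("N", "O", "S")) pi_e <- pi_e + 2
        else if (mol$element[a] == "C" && mol$charge[a] < 0L) pi_e <- pi_e + 2
        else { ok <- FALSE; break }
      }
      if (ok && pi_e %% 4 == 2) {
        if (!all(mol$aromatic[ring]) || !all(mol$bond_aromatic[rb])) changed <- TRUE
        mol$aromatic[ring] <- TRUE
        mol$bond_aromatic[rb] <- TRUE
        mol$bond_order[rb] <- 1L
      }
    }
    if (!changed) break
  }
  mol
}

#' Write a molecular graph as a SMILES string
#'
#' Produces a valid (not canonical) SMILES: aromatic atoms in lowercase,
#' bracket atoms where charges or non-standard hydrogen counts require them,
#' ring-closure digits for cycle bonds, and '.' between components.
#' @param mol a [molgraph()].
#' @return a SMILES string that reparses to an isomorphic graph.
#' @export
write_smiles <- function(mol) {
  n <- n_atoms(mol)
  if (n == 0L) return("")
  inc <- incident_bonds(mol)
  inferred <- infer_implicit_h(mol)

  bond_sym <- function(k) {
    if (mol$bond_aromatic[k]) return("")
    if (mol$bond_order[k] == 2L) return("=")
    if (mol$bond_order[k] == 3L) return("#")
    i <- mol$bond_from[k]; j <- mol$bond_to[k]
    if (mol$aromatic[i] && mol$aromatic[j]) return("-")  # e.g. biaryl bond
    ""
  }
  atom_token <- function(i) {
    el <- mol$element[i]
    arom <- mol$aromatic[i]
    sym <- if (arom) tolower(el) else el
    organic <- el %in% ORGANIC_SUBSET
    need_bracket <- !organic || mol$charge[i] != 0L || mol$nH[i] != inferred[i] ||
      (arom && !tolower(el) %in% c("b", "c", "n", "o", "p", "s"))
    if (!need_bracket) return(sym)
    h <- mol$nH[i]
    htok <- if (h == 0L) "" else if (h == 1L) "H" else paste0("H", h)
    q <- mol$charge[i]
    qtok <- if (q == 0L) "" else if (q == 1L) "+" else if (q == -1L) "-"
    else if (q > 0L) paste0("+", q) else as.character(q)
    paste0("[", sym, htok, qtok, "]")
  }

  # phase 1: spanning-tree DFS per component, collecting children and back edges
  visited <- logical(n)
  bond_seen <- logical(n_bonds(mol))
  children <- vector("list", n)      # atom -> integer vector of child bond ids
  ring_tok <- vector("list", n)      # atom -> closure tokens
  digit <- 0L
  dfs_tree <- function(start) {
    stack <- list(list(v = start, pb = 0L))
    visited[start] <<- TRUE
    order <- integer()
    # explicit-stack DFS recording tree structure
    walk <- function(v, pb) {
      for (k in inc[[v]]) {
        if (k == pb || bond_seen[k]) next
        u <- if (mol$bond_from[k] == v) mol$bond_to[k] else mol$bond_from[k]
        if (visited[u]) {
          bond_seen[k] <<- TRUE
          digit <<- digit + 1L
          dtok <- if (digit < 10L) as.character(digit) else paste0("%", sprintf("%02d", digit))
          ring_tok[[u]] <<- c(ring_tok[[u]], paste0(bond_sym(k), dtok))
          ring_tok[[v]] <<- c(ring_tok[[v]], paste0(bond_sym(k), dtok))
        } else {
          bond_seen[k] <<- TRUE
          visited[u] <<- TRUE
          children[[v]] <<- c(children[[v]], k)
          walk(u, k)
        }
      }
    }
    walk(start, 0L)
  }

  # phase 2: emit tokens following the recorded tree
  emit <- function(v) {
    toks <- atom_token(v)
    if (!is.null(ring_tok[[v]])) toks <- paste0(toks, paste(ring_tok[[v]], collapse = ""))
    ch <- children[[v]]
    nc <- length(ch)
    for (ci in seq_len(nc)) {
      k <- ch[ci]
      u <- if (mol$bond_from[k] == v) mol$bond_to[k] else mol$bond_from[k]
      sub <- paste0(bond_sym(k), emit(u))
      toks <- if (ci < nc) paste0(toks, "(", sub, ")") else paste0(toks, sub)
    }
    toks
  }

  comp <- components(mol)
  parts <- character()
  for (cid in seq_len(max(comp))) {
    start <- which(comp == cid)[1]
    dfs_tree(start)
    parts <- c(parts, emit(start))
  }
  paste(parts, collapse = ".")
}
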