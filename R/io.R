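# Library file I/O: SMILES files (one record per line, optional name,
# '#' comments) and SDF V2000 connection tables (including M CHG blocks,
# which general-purpose SDF readers may drop).

#' Read a compound library
#'
#' Order-preserving: unparseable or valence-violating records are logged in
#' the `rejections` attribute (a data.frame with `record_index`, `input_text`,
#' `reason`), not fatal.
#'
#' @param path file path.
#' @param format `"smiles"` (default; one record per line, optional
#'   whitespace-separated name, `#` comment lines ignored) or `"sdf"`
#'   (V2000; title line used as name).
#' @return list of [molgraph()] objects with attribute `rejections`.
#' @export
read_library <- function(path, format = c("smiles", "sdf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "smiles") read_smiles_file(path) else read_sdf_file(path)
}

read_smiles_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  mols <- list()
  rej <- list()
  idx <- 0L
  for (ln in lines) {
    ln <- trimws(ln)
    if (!nzchar(ln) || startsWith(ln, "#")) next
    idx <- idx + 1L
    fields <- strsplit(ln, "[ \t]+")[[1]]
    smi <- fields[1]
    nm <- if (length(fields) > 1L) paste(fields[-1], collapse = " ") else ""
    m <- tryCatch(parse_smiles(smi, name = nm), druglike_parse_error = function(e) e)
    if (inherits(m, "druglike_parse_error")) {
      rej[[length(rej) + 1L]] <- data.frame(record_index = idx, input_text = smi,
                                            reason = m$reason %||% conditionMessage(m))
    } else mols[[length(mols) + 1L]] <- m
  }
  attr(mols, "rejections") <- if (length(rej)) do.call(rbind, rej)
  else data.frame(record_index = integer(), input_text = character(), reason = character())
  mols
}

read_sdf_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  # split into records on $$$$
  is_end <- grepl("^\\${4}", lines)
  recs <- split(lines, cumsum(c(0, is_end[-length(is_end)])))
  mols <- list()
  rej <- list()
  idx <- 0L
  for (rec in recs) {
    rec <- rec[!grepl("^\\${4}", rec)]
    if (!length(rec) || all(!nzchar(trimws(rec)))) next
    idx <- idx + 1L
    m <- tryCatch(parse_v2000(rec), error = function(e) e)
    if (inherits(m, "error")) {
      rej[[length(rej) + 1L]] <- data.frame(
        record_index = idx,
        input_text = trimws(rec[1]),
        reason = conditionMessage(m))
    } else mols[[length(mols) + 1L]] <- m
  }
  attr(mols, "rejections") <- if (length(rej)) do.call(rbind, rej)
  else data.frame(record_index = integer(), input_text = character(), reason = character())
  mols
}

# minimal V2000 molfile parser: counts line, atom block (element + old-style
# charge codes), bond block (orders 1/2/3/4=aromatic), M CHG properties
parse_v2000 <- function(rec) {
  if (length(rec) < 4L) stop("truncated molfile")
  name <- trimws(rec[1])
  counts <- rec[4]
  natom <- suppressWarnings(as.integer(substr(counts, 1, 3)))
  nbond <- suppressWarnings(as.integer(substr(counts, 4, 6)))
  if (is.na(natom) || is.na(nbond)) stop("bad counts line")
  if (length(rec) < 4L + natom + nbond) stop("truncated atom/bond block")
  el <- character(natom); q <- integer(natom)
  old_charge_map <- c(`1` = 3L, `2` = 2L, `3` = 1L, `5` = -1L, `6` = -2L, `7` = -3L)
  for (i in seq_len(natom)) {
    a <- rec[4L + i]
    el[i] <- trimws(substr(a, 32, 34))
    cc <- suppressWarnings(as.integer(substr(a, 37, 39)))
    if (!is.na(cc) && cc != 0L && as.character(cc) %in% names(old_charge_map))
      q[i] <- old_charge_map[[as.character(cc)]]
    if (!nzchar(el[i])) stop("missing element symbol in atom block")
  }
  bf <- integer(nbond); bt <- integer(nbond); bo <- integer(nbond); ba <- logical(nbond)
  for (k in seq_len(nbond)) {
    b <- rec[4L + natom + k]
    bf[k] <- as.integer(substr(b, 1, 3))
    bt[k] <- as.integer(substr(b, 4, 6))
    o <- as.integer(substr(b, 7, 9))
    if (is.na(bf[k]) || is.na(bt[k]) || is.na(o)) stop("bad bond line")
    if (o == 4L) { bo[k] <- 1L; ba[k] <- TRUE } else {
      if (!o %in% 1:3) stop("unsupported bond order ", o)
      bo[k] <- o
    }
  }
  # M CHG overrides all old-style charges
  chg_lines <- grep("^M  CHG", rec, value = TRUE)
  if (length(chg_lines)) {
    q <- integer(natom)
    for (cl in chg_lines) {
      toks <- as.integer(strsplit(trimws(substr(cl, 7, nchar(cl))), "[ ]+")[[1]])
      nn <- toks[1]
      for (p in seq_len(nn)) {
        q[toks[2 * p]] <- toks[2 * p + 1L]
      }
    }
  }
  mol <- molgraph(element = el, charge = q, bond_from = bf, bond_to = bt,
                  bond_order = bo, bond_aromatic = ba, name = name)
  mol$nH <- infer_implicit_h(mol)
  mol <- perceive_aromaticity(mol)
  if (!check_valence(mol)) stop("valence violation")
  mol
}

#' Write a library as a SMILES file
#'
#' One record per line: SMILES, then the molecule name if present.
#' @param mols list of [molgraph()] objects.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_library <- function(mols, path) {
  lines <- vapply(mols, function(m) {
    smi <- write_smiles(m)
    if (nzchar(m$name)) paste(smi, m$name) else smi
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write a rejection log as CSV
#' @param mols result of [read_library()].
#' @param path output CSV path (columns `record_index`, `input_text`, `reason`).
#' @return `path`, invisibly.
#' @export
write_rejection_log <- function(mols, path) {
  utils::write.csv(attr(mols, "rejections"), path, row.names = FALSE)
  invisible(path)
}
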