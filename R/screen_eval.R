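# Screening evaluation: confusion counts, the six classification statistics
# (sensitivity, specificity, the two predictive values, global accuracy and
# the Matthews correlation coefficient), exhaustive single-descriptor
# threshold search, and descriptor ranking.

#' Confusion counts of a binary screen
#'
#' @param predicted logical vector of screen outcomes (`TRUE` = predicted
#'   drug-like).
#' @param labels logical vector of reference labels (`TRUE` = drug-like).
#' @return object of class `confusion_counts`: list with `TP`, `TN`, `FP`,
#'   `FN`.
#' @export
confusion <- function(predicted, labels) {
  if (length(predicted) != length(labels)) stop("length mismatch")
  if (!length(predicted)) stop("empty input")
  predicted <- as.logical(predicted); labels <- as.logical(labels)
  structure(list(
    TP = sum(predicted & labels), TN = sum(!predicted & !labels),
    FP = sum(predicted & !labels), FN = sum(!predicted & labels)
  ), class = "confusion_counts")
}

#' @rdname confusion
#' @param TP,TN,FP,FN non-negative integer counts.
#' @export
confusion_counts <- function(TP, TN, FP, FN) {
  stopifnot(TP >= 0, TN >= 0, FP >= 0, FN >= 0, TP + TN + FP + FN > 0)
  structure(list(TP = TP, TN = TN, FP = FP, FN = FN), class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion: TP=%d TN=%d FP=%d FN=%d>\n", x$TP, x$TN, x$FP, x$FN))
  invisible(x)
}

#' Classification statistics from confusion counts
#'
#' `SE = TP/(TP+FN)`, `SP = TN/(TN+FP)`, `PRE1 = TP/(TP+FP)` (positive
#' predictive value), `PRE2 = TN/(TN+FN)` (negative predictive value),
#' `GA = (TP+TN)/total`, and the Matthews correlation coefficient
#' `C = (TP*TN - FN*FP) / sqrt((TP+FN)(TP+FP)(TN+FN)(TN+FP))`. A statistic
#' with a zero denominator is returned as `NA` and named in the `flags`
#' attribute.
#' @param cc a [confusion_counts()] object (or list with TP/TN/FP/FN).
#' @return named numeric vector `SE`, `SP`, `PRE1`, `PRE2`, `GA`, `C` with a
#'   `flags` attribute.
#' @export
classification_metrics <- function(cc) {
  tp <- as.numeric(cc$TP); tn <- as.numeric(cc$TN)
  fp <- as.numeric(cc$FP); fn <- as.numeric(cc$FN)
  total <- tp + tn + fp + fn
  if (total == 0) stop("no evaluated molecules")
  flags <- character()
  div <- function(num, den, nm) {
    if (den == 0) { flags <<- c(flags, nm); NA_real_ } else num / den
  }
  denom_c <- (tp + fn) * (tp + fp) * (tn + fn) * (tn + fp)
  res <- c(SE = div(tp, tp + fn, "SE"),
           SP = div(tn, tn + fp, "SP"),
           PRE1 = div(tp, tp + fp, "PRE1"),
           PRE2 = div(tn, tn + fn, "PRE2"),
           GA = (tp + tn) / total,
           C = if (denom_c == 0) { flags <- c(flags, "C"); NA_real_ }
           else (tp * tn - fn * fp) / sqrt(denom_c))
  attr(res, "flags") <- flags
  res
}

#' Exhaustive threshold grid search for one descriptor
#'
#' Scans every decision threshold of a single descriptor: candidate cutoffs
#' are the midpoints of adjacent distinct values of the pooled data plus one
#' cutoff below the minimum and one above the maximum (equivalent to an
#' exhaustive scan over all distinct classifications), in both directions
#' when `direction = "auto"`. Undefined (`NA`) values are excluded and
#' counted. Ties on the criterion are broken toward the smaller cutoff, then
#' toward `below_is_positive`.
#'
#' @param values_pos descriptor values of the positive (drug-like) class.
#' @param values_neg descriptor values of the negative class.
#' @param descriptor_name name recorded in the returned filter.
#' @param direction `"auto"` (default), `"below_is_positive"` or
#'   `"above_is_positive"`.
#' @param criterion `"GA"` (global accuracy, default) or `"C"` (Matthews).
#' @return list with `filter` (a [threshold_filter()]), `metrics` (from
#'   [classification_metrics()]), `counts` (a [confusion_counts()]) and
#'   `n_excluded` (undefined values dropped).
#' @export
grid_search_threshold <- function(values_pos, values_neg,
                                  descriptor_name = "descriptor",
                                  direction = c("auto", "below_is_positive",
                                                "above_is_positive"),
                                  criterion = c("GA", "C")) {
  direction <- match.arg(direction)
  criterion <- match.arg(criterion)
  n_excluded <- sum(is.na(values_pos)) + sum(is.na(values_neg))
  values_pos <- values_pos[!is.na(values_pos)]
  values_neg <- values_neg[!is.na(values_neg)]
  if (!length(values_pos) || !length(values_neg))
    stop("a class has no defined descriptor values")

  pooled <- sort(unique(c(values_pos, values_neg)))
  cuts <- if (length(pooled) == 1L) c(pooled - 1, pooled + 1)
  else c(pooled[1] - 1, (pooled[-length(pooled)] + pooled[-1]) / 2,
         pooled[length(pooled)] + 1)

  sp <- sort(values_pos); sn <- sort(values_neg)
  npos <- length(sp); nneg <- length(sn)
  # counts strictly below each cutoff (cutoffs never coincide with data values)
  pos_below <- findInterval(cuts, sp)
  neg_below <- findInterval(cuts, sn)

  eval_dir <- function(dir) {
    if (dir == "below_is_positive") {
      tp <- pos_below; fn <- npos - tp
      fp <- neg_below; tn <- nneg - fp
    } else {
      tp <- npos - pos_below; fn <- pos_below
      fp <- nneg - neg_below; tn <- neg_below
    }
    ga <- (tp + tn) / (npos + nneg)
    if (criterion == "GA") crit <- ga
    else {
      den <- (tp + fn) * (tp + fp) * (tn + fn) * (tn + fp)
      crit <- ifelse(den == 0, -Inf, (tp * tn - fn * fp) / sqrt(den))
    }
    list(crit = crit, tp = tp, tn = tn, fp = fp, fn = fn)
  }

  dirs <- if (direction == "auto") c("below_is_positive", "above_is_positive")
  else direction
  best <- NULL
  for (dir in dirs) {
    ev <- eval_dir(dir)
    i <- which.max(ev$crit)  # ties: smaller cutoff wins (cuts are ascending)
    cand <- list(dir = dir, cutoff = cuts[i], crit = ev$crit[i],
                 counts = confusion_counts(ev$tp[i], ev$tn[i], ev$fp[i], ev$fn[i]))
    if (is.null(best) || cand$crit > best$crit + 1e-15) best <- cand
    # equal criterion: keep below_is_positive (first in dirs), then smaller cutoff
  }
  list(filter = threshold_filter_unchecked(descriptor_name, best$cutoff, best$dir),
       metrics = classification_metrics(best$counts),
       counts = best$counts,
       n_excluded = n_excluded)
}

# internal constructor that skips the descriptor-name whitelist (grid search
# is usable on arbitrary columns)
threshold_filter_unchecked <- function(descriptor_name, cutoff, direction) {
  structure(list(descriptor_name = descriptor_name, cutoff = cutoff,
                 direction = direction), class = "threshold_filter")
}

#' Rank descriptors by single-threshold classification performance
#'
#' Runs [grid_search_threshold()] on every descriptor column and sorts by the
#' criterion, descending. Columns with an entirely undefined class are
#' skipped with a message.
#'
#' @param table descriptor table (data.frame/tibble; non-descriptor columns
#'   `molecule` and `flags` are ignored).
#' @param labels logical vector, `TRUE` for the drug-like reference class.
#' @param criterion `"GA"` or `"C"`.
#' @return tibble with one row per descriptor: `descriptor`, `direction`,
#'   `cutoff`, `TP`, `TN`, `FP`, `FN`, `SE`, `SP`, `PRE1`, `PRE2`, `GA`, `C`,
#'   `n_excluded`, sorted by the criterion.
#' @export
rank_descriptors <- function(table, labels, criterion = c("GA", "C")) {
  criterion <- match.arg(criterion)
  labels <- as.logical(labels)
  stopifnot(nrow(table) == length(labels))
  cols <- setdiff(colnames(table), c("molecule", "flags"))
  rows <- list()
  for (cn in cols) {
    v <- table[[cn]]
    if (!is.numeric(v)) next
    res <- tryCatch(
      grid_search_threshold(v[labels], v[!labels], descriptor_name = cn,
                            criterion = criterion),
      error = function(e) NULL)
    if (is.null(res)) {
      message("descriptor ", cn, " skipped (no defined values in a class)")
      next
    }
    m <- res$metrics
    rows[[length(rows) + 1L]] <- tibble::tibble(
      descriptor = cn, direction = res$filter$direction,
      cutoff = res$filter$cutoff,
      TP = res$counts$TP, TN = res$counts$TN, FP = res$counts$FP,
      FN = res$counts$FN,
      SE = m[["SE"]], SP = m[["SP"]], PRE1 = m[["PRE1"]], PRE2 = m[["PRE2"]],
      GA = m[["GA"]], C = m[["C"]], n_excluded = res$n_excluded)
  }
  out <- do.call(rbind, rows)
  out[order(-out[[criterion]]), ]
}
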