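# Library profiling: distribution summaries, inter-library comparison,
# simple correlation, and standardized PCA with score plots.

#' Profile a descriptor table
#'
#' Per-descriptor mean, sample SD and histogram over non-missing values.
#' Default bin widths follow the common presentation of these panels (MW 50
#' Da, logP-type 0.5, PSA 10 A^2, counts 1) and can be overridden.
#'
#' @param table descriptor table (tibble/data.frame; `molecule` and `flags`
#'   columns ignored).
#' @param name library name.
#' @param bin_widths named numeric vector of histogram bin widths; unnamed
#'   descriptors fall back to a Freedman-Diaconis-style default.
#' @return object of class `library_profile`: list with `name`, `n`, `stats`
#'   (tibble: descriptor, mean, sd, n_defined), `histograms` (named list of
#'   lists with `breaks` and `freq` summing to 1), and `data` (the numeric
#'   columns, kept for distribution tests).
#' @export
profile_library <- function(table, name = "library", bin_widths = NULL) {
  cols <- setdiff(colnames(table), c("molecule", "flags"))
  cols <- cols[vapply(table[cols], is.numeric, logical(1))]
  if (!nrow(table) || !length(cols)) stop("empty descriptor table")
  defaults <- c(MW = 50, AlogP = 0.5, "logD7.4" = 0.5, logS = 0.5, PSA = 10,
                MSA = 10)
  stats <- lapply(cols, function(cn) {
    v <- table[[cn]]; v <- v[!is.na(v)]
    tibble::tibble(descriptor = cn, mean = mean(v), sd = stats::sd(v),
                   n_defined = length(v))
  })
  hists <- lapply(cols, function(cn) {
    v <- table[[cn]]; v <- v[!is.na(v)]
    if (!length(v)) return(list(breaks = numeric(), freq = numeric()))
    bw <- if (!is.null(bin_widths) && cn %in% names(bin_widths)) bin_widths[[cn]]
    else if (cn %in% names(defaults)) defaults[[cn]]
    else {
      iqr <- stats::IQR(v)
      if (iqr > 0) 2 * iqr / length(v)^(1 / 3) else 1
    }
    lo <- floor(min(v) / bw) * bw
    breaks <- seq(lo, max(v) + bw, by = bw)
    h <- graphics::hist(v, breaks = breaks, plot = FALSE)
    list(breaks = h$breaks, freq = h$counts / length(v))
  })
  names(hists) <- cols
  structure(list(name = name, n = nrow(table),
                 stats = do.call(rbind, stats), histograms = hists,
                 data = table[cols]),
            class = "library_profile")
}

#' @export
print.library_profile <- function(x, ...) {
  cat(sprintf("<library_profile %s: n=%d, %d descriptors>\n",
              x$name, x$n, nrow(x$stats)))
  invisible(x)
}

#' Compare library profiles
#'
#' Pairwise mean differences and two-sample Kolmogorov-Smirnov statistics
#' (computed from the raw columns retained in each profile) for every
#' descriptor shared by all profiles.
#' @param profiles list of [profile_library()] results (>= 2) over the same
#'   descriptor names.
#' @return tibble with `descriptor`, `library_a`, `library_b`, `mean_a`,
#'   `mean_b`, `mean_diff` (a - b) and `ks` columns.
#' @export
compare_libraries <- function(profiles) {
  stopifnot(length(profiles) >= 2L)
  namesets <- lapply(profiles, function(p) p$stats$descriptor)
  common <- Reduce(intersect, namesets)
  if (!length(common)) stop("profiles share no descriptor names")
  if (!all(lengths(namesets) == length(common)))
    stop("descriptor-name mismatch between profiles")
  rows <- list()
  np <- length(profiles)
  for (a in seq_len(np - 1L)) for (b in (a + 1L):np) {
    pa <- profiles[[a]]; pb <- profiles[[b]]
    for (cn in common) {
      va <- pa$data[[cn]]; va <- va[!is.na(va)]
      vb <- pb$data[[cn]]; vb <- vb[!is.na(vb)]
      ks <- if (length(va) && length(vb))
        unname(suppressWarnings(stats::ks.test(va, vb, exact = FALSE)$statistic))
      else NA_real_
      rows[[length(rows) + 1L]] <- tibble::tibble(
        descriptor = cn, library_a = pa$name, library_b = pb$name,
        mean_a = mean(va), mean_b = mean(vb), mean_diff = mean(va) - mean(vb),
        ks = ks)
    }
  }
  do.call(rbind, rows)
}

#' Least-squares line and Pearson correlation
#' @param x,y numeric vectors of equal length >= 3.
#' @return named numeric vector with `slope`, `intercept`, `r`.
#' @export
correlate <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (stats::var(x) == 0) stop("zero variance in x")
  slope <- stats::cov(x, y) / stats::var(x)
  c(slope = slope, intercept = mean(y) - slope * mean(x),
    r = stats::cor(x, y))
}

#' Standardized principal component analysis of a descriptor table
#'
#' Columns are standardized to zero mean and unit variance (correlation-matrix
#' PCA: descriptors live on wildly different scales), constant columns are
#' dropped, missing (flagged-undefined) values are imputed with the column
#' mean, and the sign of each loading vector is fixed so its largest-magnitude
#' entry is positive.
#'
#' @param table descriptor table (tibble/data.frame; `molecule` and `flags`
#'   ignored).
#' @param n_components number of components to retain.
#' @return object of class `pca_result`: `loadings` (descriptor x component),
#'   `scores` (molecule x component), `explained` (variance fractions,
#'   non-increasing), `center`, `scale`, `columns`.
#' @export
run_pca <- function(table, n_components = 2L) {
  cols <- setdiff(colnames(table), c("molecule", "flags"))
  cols <- cols[vapply(table[cols], is.numeric, logical(1))]
  X <- as.matrix(table[cols])
  # mean-impute flagged/missing values
  for (j in seq_len(ncol(X))) {
    nas <- is.na(X[, j])
    if (any(nas)) X[nas, j] <- mean(X[, j], na.rm = TRUE)
  }
  keep <- apply(X, 2, function(v) stats::sd(v) > 0)
  if (sum(keep) < n_components)
    stop("fewer non-constant columns (", sum(keep), ") than components requested")
  X <- X[, keep, drop = FALSE]
  pc <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  k <- n_components
  load <- pc$rotation[, seq_len(k), drop = FALSE]
  scores <- pc$x[, seq_len(k), drop = FALSE]
  # deterministic sign convention
  for (j in seq_len(k)) {
    i <- which.max(abs(load[, j]))
    if (load[i, j] < 0) {
      load[, j] <- -load[, j]
      scores[, j] <- -scores[, j]
    }
  }
  expl <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(loadings = load, scores = scores,
                 explained = expl[seq_len(k)],
                 explained_all = expl,
                 center = pc$center, scale = pc$scale, columns = colnames(X)),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("<pca_result: %d components over %d descriptors; explained %s>\n",
              ncol(x$loadings), length(x$columns),
              paste(sprintf("%.1f%%", 100 * x$explained), collapse = ", ")))
  invisible(x)
}

#' Project a descriptor table onto a fitted PCA basis
#' @param pca a [run_pca()] result.
#' @param table descriptor table with the columns the PCA was fitted on.
#' @return score matrix (molecules x components).
#' @export
project_pca <- function(pca, table) {
  X <- as.matrix(table[pca$columns])
  for (j in seq_len(ncol(X))) {
    nas <- is.na(X[, j])
    if (any(nas)) X[nas, j] <- pca$center[j]
  }
  Xs <- sweep(sweep(X, 2, pca$center), 2, pca$scale, "/")
  Xs %*% pca$loadings
}

#' Score plot panels for several libraries on one PCA basis
#'
#' Fits nothing: the PCA must be fitted on the pooled table so all panels
#' share one basis; each library is projected with [project_pca()] and drawn
#' in its own facet with shared axis limits.
#' @param pca a [run_pca()] result fitted on pooled data.
#' @param tables named list of descriptor tables, one per library.
#' @param components which two components to draw.
#' @param alpha point transparency.
#' @return a ggplot object with one facet per library.
#' @export
plot_scores <- function(pca, tables, components = c(1L, 2L), alpha = 0.4) {
  stopifnot(length(components) == 2L)
  dfs <- lapply(names(tables), function(nm) {
    sc <- project_pca(pca, tables[[nm]])
    if (!nrow(sc)) return(tibble::tibble(PCx = numeric(), PCy = numeric(),
                                         library = character()))
    tibble::tibble(PCx = sc[, components[1]], PCy = sc[, components[2]],
                   library = nm)
  })
  df <- do.call(rbind, dfs)
  df$library <- factor(df$library, levels = names(tables))
  labs_x <- sprintf("PC%d (%.1f%%)", components[1], 100 * pca$explained[components[1]])
  labs_y <- sprintf("PC%d (%.1f%%)", components[2], 100 * pca$explained[components[2]])
  ggplot2::ggplot(df, ggplot2::aes(x = PCx, y = PCy)) +
    ggplot2::geom_point(size = 0.6, alpha = alpha) +
    ggplot2::facet_wrap(~library, drop = FALSE) +
    ggplot2::labs(x = labs_x, y = labs_y) +
    ggplot2::theme_bw()
}
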