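test_that("confusion tallies match hand counts", {
  cc <- confusion(rep(c(TRUE, FALSE), c(10, 10)), rep(c(TRUE, FALSE), c(10, 10)))
  expect_equal(unlist(cc[c("TP", "TN", "FP", "FN")]), c(TP = 10, TN = 10, FP = 0, FN = 0))
  inv <- confusion(rep(c(FALSE, TRUE), c(10, 10)), rep(c(TRUE, FALSE), c(10, 10)))
  expect_equal(inv$TP + inv$TN, 0)
  # six-item toy case tallied by hand
  pred <- c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE)
  lab <- c(TRUE, FALSE, TRUE, FALSE, TRUE, TRUE)
  cc <- confusion(pred, lab)
  expect_equal(unlist(cc[c("TP", "TN", "FP", "FN")]), c(TP = 2, TN = 1, FP = 1, FN = 2))
  expect_error(confusion(TRUE, c(TRUE, FALSE)), "length mismatch")
})

test_that("classification statistics match direct evaluation of their formulas", {
  perfect <- classification_metrics(confusion_counts(50, 50, 0, 0))
  expect_equal(unname(perfect[c("SE", "SP", "GA", "C")]), c(1, 1, 1, 1))

  m <- classification_metrics(confusion_counts(TP = 40, TN = 30, FP = 20, FN = 10))
  expect_equal(m[["SE"]], 40 / 50)
  expect_equal(m[["SP"]], 30 / 50)
  expect_equal(m[["PRE1"]], 40 / 60)
  expect_equal(m[["PRE2"]], 30 / 40)
  expect_equal(m[["GA"]], 0.7)
  expect_equal(m[["C"]], (40 * 30 - 10 * 20) / sqrt(50 * 60 * 40 * 50),
               tolerance = 1e-12)

  # degenerate: nothing predicted correctly; all marginals are 10, so the
  # Matthews coefficient is exactly -1 (anti-perfect), and GA is 0
  d <- classification_metrics(confusion_counts(0, 0, 10, 10))
  expect_equal(d[["GA"]], 0)
  expect_equal(d[["C"]], -1)
  # truly undefined statistics are flagged, not NaN
  f <- classification_metrics(confusion_counts(0, 10, 0, 10))
  expect_true(is.na(f[["PRE1"]]))
  expect_true("PRE1" %in% attr(f, "flags"))
  expect_true(is.na(f[["C"]]))
})

test_that("swapping classes swaps SE/SP and PRE1/PRE2, preserving GA and |C|", {
  set.seed(29)
  for (i in 1:40) {
    v <- sample(0:50, 4, replace = TRUE)
    if (sum(v) == 0) next
    a <- classification_metrics(confusion_counts(v[1], v[2], v[3], v[4]))
    b <- classification_metrics(confusion_counts(v[2], v[1], v[4], v[3]))
    expect_equal(a[["SE"]], b[["SP"]])
    expect_equal(a[["PRE1"]], b[["PRE2"]])
    expect_equal(a[["GA"]], b[["GA"]])
    if (!is.na(a[["C"]])) expect_equal(abs(a[["C"]]), abs(b[["C"]]))
  }
})

test_that("grid search separates separable data and not identical data", {
  g <- grid_search_threshold(c(0.1, 0.2, 0.3), c(0.4, 0.5, 0.6))
  expect_equal(g$metrics[["GA"]], 1)
  expect_equal(g$filter$direction, "below_is_positive")
  expect_gt(g$filter$cutoff, 0.3); expect_lt(g$filter$cutoff, 0.4)

  same <- c(1, 2, 3, 4, 5)
  g2 <- grid_search_threshold(same, same)
  expect_equal(g2$metrics[["GA"]], 0.5)

  # undefined values are excluded and counted
  g3 <- grid_search_threshold(c(0.1, NA, 0.2), c(0.5, 0.6, NA))
  expect_equal(g3$n_excluded, 2)
  expect_error(grid_search_threshold(c(NA_real_), c(1, 2)), "no defined")
})

test_that("grid search equals the brute-force threshold scan", {
  set.seed(37)
  for (i in 1:20) {
    pos <- round(rnorm(100, mean = runif(1, -1, 1)), 2)
    neg <- round(rnorm(100, mean = runif(1, -1, 1)), 2)
    g <- grid_search_threshold(pos, neg)
    expect_equal(g$metrics[["GA"]], brute_force_best_ga(pos, neg),
                 label = paste("instance", i))
  }
})

test_that("the optimal cutoff is translation-equivariant", {
  set.seed(41)
  pos <- rnorm(80); neg <- rnorm(80, 1)
  g0 <- grid_search_threshold(pos, neg)
  g1 <- grid_search_threshold(pos + 5, neg + 5)
  expect_equal(g1$filter$cutoff, g0$filter$cutoff + 5, tolerance = 1e-9)
  expect_equal(g1$metrics[["GA"]], g0$metrics[["GA"]])
  expect_equal(g1$filter$direction, g0$filter$direction)
})

test_that("descriptor ranking puts informative columns first, deterministically", {
  set.seed(43)
  n <- 300
  labels <- rep(c(TRUE, FALSE), each = n)
  tab <- tibble::tibble(
    informative = c(rnorm(n, 0), rnorm(n, 2)),
    noise1 = rnorm(2 * n),
    noise2 = rnorm(2 * n))
  rk <- rank_descriptors(tab, labels)
  expect_equal(rk$descriptor[1], "informative")
  expect_gt(rk$GA[1], 0.75)
  expect_true(all(rk$GA[-1] < 0.6))
  rk2 <- rank_descriptors(tab, labels)
  expect_identical(rk, rk2)

  # all-noise table: accuracies stay near chance
  noise <- tibble::tibble(a = rnorm(2 * n), b = rnorm(2 * n))
  rkn <- rank_descriptors(noise, labels)
  expect_true(all(abs(rkn$GA - 0.5) < 0.1))
})
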