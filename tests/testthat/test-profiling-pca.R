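test_that("library profiles summarise columns and ignore row order", {
  tab <- tibble::tibble(a = c(0, 2), b = c(3, 3))
  p <- profile_library(tab, "toy")
  expect_equal(p$stats$mean[p$stats$descriptor == "a"], 1)
  expect_equal(p$stats$sd[p$stats$descriptor == "a"], sqrt(2))
  expect_equal(p$stats$sd[p$stats$descriptor == "b"], 0)
  expect_length(p$histograms$b$freq[p$histograms$b$freq > 0], 1)
  expect_equal(sum(p$histograms$a$freq), 1, tolerance = 1e-9)

  set.seed(47)
  big <- tibble::tibble(x = rnorm(50), y = runif(50))
  p1 <- profile_library(big, "l")
  p2 <- profile_library(big[sample(50), ], "l")
  expect_equal(p1$stats, p2$stats)
  expect_error(profile_library(tibble::tibble()), "empty")
})

test_that("library comparison reports mean shifts and KS statistics", {
  tab <- tibble::tibble(x = rnorm(100))
  pa <- profile_library(tab, "A"); pb <- profile_library(tab, "B")
  cmp <- compare_libraries(list(pa, pb))
  expect_equal(cmp$mean_diff, 0)
  expect_equal(cmp$ks, 0)

  shifted <- profile_library(tibble::tibble(x = tab$x + 100), "C")
  cmp2 <- compare_libraries(list(pa, shifted))
  expect_equal(cmp2$mean_diff, -100, tolerance = 1e-9)
  expect_equal(cmp2$ks, 1)  # disjoint supports

  expect_error(compare_libraries(list(pa, profile_library(tibble::tibble(z = 1:5), "D"))),
               "mismatch|share no")
})

test_that("class contrasts carry the expected signs in profile comparisons", {
  wanted <- c("N_O", "N_N", "N_rot", "N_aromatic", "N_Bridge")
  nat <- compute_descriptor_table(test_library("naturallike", n = 150, seed = 91),
                                  which = wanted)
  drg <- compute_descriptor_table(test_library("druglike", n = 150, seed = 92),
                                  which = wanted)
  cmp <- compare_libraries(list(profile_library(nat[wanted], "natural"),
                                profile_library(drg[wanted], "drug")))
  diff <- setNames(cmp$mean_diff, cmp$descriptor)  # natural - drug
  expect_gt(diff[["N_O"]], 0)
  expect_lt(diff[["N_N"]], 0)
  expect_lt(diff[["N_rot"]], 0)
  expect_lt(diff[["N_aromatic"]], 0)
  expect_gt(diff[["N_Bridge"]], 0)
})

test_that("least-squares correlation matches exact and symmetric cases", {
  x <- seq_len(10)
  r <- correlate(x, 2 * x + 1)
  expect_equal(unname(r), c(2, 1, 1), tolerance = 1e-12)
  set.seed(53)
  a <- rnorm(10000); b <- rnorm(10000)
  expect_lt(abs(correlate(a, b)[["r"]]), 0.05)
  expect_equal(correlate(a, b)[["r"]], correlate(b, a)[["r"]])
  expect_error(correlate(rep(1, 5), rnorm(5)), "zero variance")
})

test_that("standardized PCA has orthonormal loadings and sane explained fractions", {
  set.seed(59)
  # variance along one direction only
  t1 <- tibble::tibble(x = rnorm(500))
  t1$y <- 2 * t1$x; t1$z <- -t1$x
  p1 <- run_pca(t1, 1)
  expect_gt(p1$explained[1], 0.999)

  # isotropic: each of k columns explains ~ 1/k
  k <- 5
  iso <- tibble::as_tibble(as.data.frame(matrix(rnorm(10000 * k), ncol = k)))
  pk <- run_pca(iso, k)
  expect_true(all(abs(pk$explained - 1 / k) < 0.02))
  expect_equal(sum(pk$explained_all), 1, tolerance = 1e-8)
  expect_equal(crossprod(pk$loadings), diag(k), tolerance = 1e-8,
               ignore_attr = TRUE)

  # duplicated column loads identically on PC1
  dup <- tibble::tibble(a = rnorm(300))
  dup$b <- dup$a; dup$c <- rnorm(300)
  pd <- run_pca(dup, 2)
  expect_equal(pd$loadings["a", 1], pd$loadings["b", 1], tolerance = 1e-9)

  # affine rescaling of a column changes nothing (standardization)
  sc <- iso; sc$V1 <- sc$V1 * 1000 + 77
  ps <- run_pca(sc, k)
  expect_equal(ps$explained, pk$explained, tolerance = 1e-9)
  expect_error(run_pca(tibble::tibble(a = rep(1, 10), b = rnorm(10)), 2),
               "non-constant")
})

test_that("score plots share one pooled basis across per-library panels", {
  set.seed(61)
  tabs <- list(A = tibble::tibble(x = rnorm(60), y = rnorm(60), z = rnorm(60)),
               B = tibble::tibble(x = rnorm(60, 2), y = rnorm(60), z = rnorm(60)),
               C = tibble::tibble(x = numeric(), y = numeric(), z = numeric()))
  pooled <- do.call(rbind, tabs)
  pca <- run_pca(pooled, 2)
  # projection of pooled data reproduces the fitted scores
  expect_equal(project_pca(pca, pooled), pca$scores, tolerance = 1e-9)
  p <- plot_scores(pca, tabs)
  expect_s3_class(p, "ggplot")
  built <- ggplot2::ggplot_build(p)
  expect_equal(nrow(built$layout$layout), 3)  # one panel per library, empty included
})
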