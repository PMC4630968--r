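test_that("distance recovery score is invariant to isometries and scaling", {
  set.seed(100)
  Z <- matrix(rnorm(60), 30, 2)
  th <- 1.1
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  expect_equal(distance_recovery_score(Z, Z %*% R)$spearman, 1.0)
  expect_equal(distance_recovery_score(Z, 2 * Z + 3)$spearman, 1.0)
  expect_equal(distance_recovery_score(Z, Z[, 2:1])$spearman, 1.0)
  expect_error(distance_recovery_score(Z[1:2, ], Z[1:2, ]), "3")
  sc <- distance_recovery_score(Z, Z %*% R)
  expect_true(isSymmetric(sc$F_true))
  expect_true(all(diag(sc$F_true) == 0))
})

test_that("unrelated embeddings score near zero", {
  hits <- sum(sapply(1:20, function(s) {
    set.seed(300 + s)
    a <- matrix(rnorm(300), 150, 2)
    b <- matrix(rnorm(300), 150, 2)
    abs(distance_recovery_score(a, b)$spearman) < 0.15
  }))
  expect_gte(hits, 15)
})

test_that("histogram divergence has the right arithmetic and bounds", {
  set.seed(101)
  x <- rnorm(500)
  expect_equal(histogram_divergence(x, x), 0)
  # disjoint supports give the maximum of 2
  expect_equal(histogram_divergence(runif(200, 0, 1), runif(200, 5, 6)), 2)
  # half-overlap case: h = (.5, .5), hhat = (1, 0) over shared bins
  obs <- c(rep(0.25, 50), rep(0.75, 50))
  pred <- rep(0.25, 80)
  expect_equal(histogram_divergence(obs, pred, n_bins = 2,
                                    breaks = c(0, 0.5, 1)), 1.0)
  # identical constants: degenerate range convention
  expect_equal(histogram_divergence(rep(2, 5), rep(2, 9)), 0)
  # always within [0, 2]
  for (s in 1:10) {
    set.seed(s)
    d <- histogram_divergence(rnorm(100, s / 5), rnorm(100))
    expect_gte(d, 0)
    expect_lte(d, 2)
  }
})

test_that("histogram divergence obeys the triangle property on shared bins", {
  set.seed(102)
  breaks <- seq(-4, 4, length.out = 31)
  for (r in 1:5) {
    a <- rnorm(200); b <- rnorm(200, 0.5); c <- rnorm(200, 1)
    dab <- histogram_divergence(a, b, breaks = breaks)
    dbc <- histogram_divergence(b, c, breaks = breaks)
    dac <- histogram_divergence(a, c, breaks = breaks)
    expect_lte(dac, dab + dbc + 1e-12)
  }
})

test_that("predictive study splits 70/30, is seeded, and rejects PCA", {
  sim <- simulate_factor_data(N = 60, D = 12, K = 2, sigma2 = 0.3,
                              lam = 0.1, seed = 103)
  y <- sim$Y[, colSums(sim$Y != 0) > 0, drop = FALSE]
  pc <- suppressWarnings(
    predictive_fit_study(y, K = 2, methods = c("zifa", "fa"), seed = 5,
                         max_iter = 40))
  expect_equal(pc$n_train, 42)
  expect_equal(pc$n_test, 18)
  expect_equal(nrow(pc$divergence), ncol(y))
  expect_true(all(pc$divergence >= 0 & pc$divergence <= 2))
  pc2 <- suppressWarnings(
    predictive_fit_study(y, K = 2, methods = c("zifa", "fa"), seed = 5,
                         max_iter = 40))
  expect_identical(pc$divergence, pc2$divergence)
  expect_error(predictive_fit_study(y, methods = "pca"))
  expect_error(predictive_fit_study(y[1:8, ]), "10 cells")
})

test_that("zero-inflated fits beat Gaussian fits where dropout is heavy", {
  sim <- simulate_factor_data(N = 100, D = 30, K = 3, sigma2 = 0.3,
                              lam = 0.05, seed = 104)
  y <- sim$Y[, colSums(sim$Y != 0) > 0, drop = FALSE]
  pc <- suppressWarnings(
    predictive_fit_study(y, K = 3, methods = c("zifa", "fa"), seed = 1,
                         max_iter = 60))
  expect_gt(pc$win_fraction[["fa"]], 0.8)
})

test_that("consistency study yields n(n-1)/2 correlations per method", {
  sim <- simulate_factor_data(N = 40, D = 30, K = 2, sigma2 = 0.3,
                              lam = 0.1, seed = 105)
  cs <- consistency_study(sim$Y, n_repeats = 4, subset_size = 15,
                          methods = "ppca", K = 2, seed = 1)
  expect_length(cs$methods$ppca$correlations, 6)
  cs2 <- consistency_study(sim$Y, n_repeats = 2, subset_size = 15,
                           methods = "ppca", K = 2, seed = 1)
  expect_length(cs2$methods$ppca$correlations, 1)
  expect_error(consistency_study(sim$Y, subset_size = 999), "exceeds")
})

test_that("separability study reports per-subset rates with a baseline", {
  sim <- simulate_cluster_scaffold(N = 90, D = 80, K = 3, n_clusters = 3,
                                   separation = 3, sigma2 = 0.3, lam = 0.1,
                                   seed = 106)
  rep1 <- suppressWarnings(
    separability_study(sim, K_out = 3, subset_size = 60, n_subsets = 2,
                       classifiers = c("lda", "qda"), seed = 1,
                       max_iter = 30))
  r <- rep1$rates
  expect_setequal(unique(r$method), c("pca", "zifa", "exact_pca"))
  expect_setequal(unique(r$classifier), c("lda", "qda"))
  expect_equal(nrow(r), 2 * 3 * 2)
  expect_true(all(r$error >= 0 & r$error <= 1, na.rm = TRUE))
  sim_nolab <- simulate_factor_data(seed = 1)
  expect_error(separability_study(sim_nolab), "labels")
})
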