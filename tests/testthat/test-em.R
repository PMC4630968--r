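test_that("gene blocks partition the genes and chunk correctly", {
  b <- make_gene_blocks(500, 50, seed = 1)
  expect_length(b, 10)
  expect_true(all(lengths(b) == 50))
  expect_setequal(unlist(b), 1:500)
  b2 <- make_gene_blocks(53, 50, seed = 2)
  expect_equal(sort(lengths(b2), decreasing = TRUE), c(50, 3))
  expect_length(make_gene_blocks(20, 20, seed = 3), 1)
  expect_identical(make_gene_blocks(100, 7, seed = 4),
                   make_gene_blocks(100, 7, seed = 4))
})

test_that("E-step reduces to factor-analysis posteriors on zero-free data", {
  p <- rand_params(6, 2, lam = 5, seed = 21)
  y <- abs(zifa_sample(p, 15, seed = 22)$X) + 1
  post <- zifa_e_step(p, y)
  # FA posterior: (I + A' W^-1 A)^-1 A' W^-1 (y - mu)
  M <- diag(2) + t(p$A) %*% (p$A / p$sigma2)
  Ez_fa <- t(solve(M, t(p$A / p$sigma2) %*% (t(y) - p$mu)))
  expect_equal(post$Ez, Ez_fa, tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(post$Vz[, , 1], solve(M), tolerance = 1e-10)
  expect_identical(post$EX, y)
})

test_that("E-step moments match an importance-sampling oracle on toy instances", {
  for (inst in 1:2) {
    D <- 2 + inst  # 3 then 4 genes
    p <- rand_params(D, 1, lam = 0.3, seed = 30 + inst)
    y <- zifa_sample(p, 10, seed = 40 + inst)$Y
    post <- zifa_e_step(p, y)
    set.seed(50 + inst)
    for (i in seq_len(nrow(y))) {
      or <- is_cell_moments(p, y[i, ], n_draw = 2e5)
      expect_within_3se(post$Ez[i, 1], or$Ez)
      expect_within_3se(post$Vz[1, 1, i] + post$Ez[i, 1]^2, or$Ez2)
      for (j in which(y[i, ] == 0)) {
        expect_within_3se(post$EX[i, j], or[[paste0("Ex", j)]])
        expect_within_3se(post$EX2[i, j], or[[paste0("Ex2_", j)]])
        expect_within_3se(post$EXZ[i, j, 1], or[[paste0("Exz", j)]])
      }
    }
  }
})

test_that("posterior second moments are coherent", {
  p <- rand_params(10, 3, lam = 0.2, seed = 25)
  y <- zifa_sample(p, 30, seed = 26)$Y
  post <- zifa_e_step(p, y)
  for (i in c(1, 15, 30))
    expect_true(all(eigen(post$Vz[, , i], symmetric = TRUE,
                          only.values = TRUE)$values > 0))
  zmask <- y == 0
  expect_true(all(post$EX2[zmask] >= post$EX[zmask]^2))
})

test_that("an all-zero cell is shrunk toward the prior", {
  p <- rand_params(6, 1, lam = 0.1, seed = 27)
  y <- zifa_sample(p, 4, seed = 28)$Y
  y[1, ] <- 0
  y[2, ] <- pmax(abs(y[2, ]), 0.5)
  post <- zifa_e_step(p, y)
  expect_lt(abs(post$Ez[1, 1]), 0.5)
  expect_gt(post$Vz[1, 1, 1], post$Vz[1, 1, 2])
})

test_that("M-step increases the expected complete log-likelihood", {
  for (s in 1:4) {
    p <- rand_params(8, 2, lam = 0.15, seed = 60 + s)
    y <- zifa_sample(p, 50, seed = 70 + s)$Y
    # start from deliberately wrong parameters
    p0 <- zifa_params(p$A * 0.5 + 0.1, p$mu * 1.2, p$sigma2 * 2, p$lam * 2)
    post <- zifa_e_step(p0, y)
    p1 <- zifa_m_step(post, y, p0)
    q0 <- zifar:::expected_complete_loglik(p0, post, y)
    q1 <- zifar:::expected_complete_loglik(p1, post, y)
    expect_gt(q1, q0)
  }
})

test_that("M-step with frozen dropout on zero-free data is the FA update", {
  p <- rand_params(5, 2, lam = 1, seed = 80)
  y <- abs(zifa_sample(p, 40, seed = 81)$X) + 1
  post <- zifa_e_step(p, y)
  up <- zifa_m_step(post, y, p)
  # classical FA M-step from the same moments
  Szz <- apply(post$Vz, c(1, 2), sum) + crossprod(post$Ez)
  Sz <- colSums(post$Ez)
  G <- rbind(cbind(Szz, Sz), c(Sz, nrow(y)))
  rhs <- cbind(t(y) %*% post$Ez, colSums(y))
  B <- t(solve(G, t(rhs)))
  expect_equal(up$A, B[, 1:2], tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(up$mu, B[, 3], tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("tied-variance M-step returns a constant noise vector", {
  p <- rand_params(7, 2, lam = 0.2, seed = 82)
  y <- zifa_sample(p, 30, seed = 83)$Y
  up <- zifa_m_step(zifa_e_step(p, y), y, p, tied_variance = TRUE)
  expect_length(unique(up$sigma2), 1)
})

test_that("initialization recovers lambda to a factor of 3 and is deterministic", {
  hits <- sum(sapply(1:6, function(s) {
    sim <- simulate_factor_data(seed = 200 + s)
    y <- sim$Y[, colSums(sim$Y != 0) > 0, drop = FALSE]
    l0 <- zifa_init(y, K = 10)$lam
    l0 > 0.1 / 3 && l0 < 0.1 * 3
  }))
  expect_gte(hits, 4)
  sim <- simulate_factor_data(seed = 1)
  expect_identical(zifa_init(sim$Y, 10), zifa_init(sim$Y, 10))
  # zero-free input falls back to the small default
  yz <- abs(matrix(rnorm(200, 3), 20, 10)) + 0.5
  expect_equal(zifa_init(yz, 2)$lam, 0.05)
  # all-zero gene is rejected with advice to pre-filter
  bad <- sim$Y
  bad[, 3] <- 0
  expect_error(zifa_init(bad, 5), "filter")
})

test_that("exact EM has a monotone log-likelihood trace and recovers lambda", {
  fits <- lapply(1:3, function(s) {
    sim <- simulate_factor_data(seed = s)
    suppressWarnings(zifa(sim$Y, K = 10, method = "exact", seed = s,
                          max_iter = 120))
  })
  for (f in fits) {
    expect_true(all(diff(f$loglik_trace) >= -1e-8 * abs(f$loglik_trace[-1])))
    expect_lt(abs(f$params$lam - 0.1) / 0.1, 0.5)
  }
})

test_that("on zero-free data the ZIFA loadings span the FA subspace", {
  sim <- simulate_factor_data(N = 120, D = 20, K = 3, sigma2 = 0.2,
                              lam = 50, seed = 31)
  y <- sim$X + 6  # shift well away from zero; no dropouts
  expect_true(all(y > 0))
  fz <- suppressWarnings(zifa(y, K = 3, method = "exact", seed = 1))
  fa <- fit_fa(y, 3)
  expect_lt(subspace_angle(fz$params$A, fa$loadings), 1e-2)
  expect_equal(fz$params$mu, unname(fa$means), tolerance = 1e-3)
})

test_that("block fit with a single block matches the exact fit", {
  sim <- simulate_factor_data(N = 60, D = 20, K = 3, sigma2 = 0.3,
                              lam = 0.1, seed = 32)
  fe <- suppressWarnings(zifa(sim$Y, K = 3, method = "exact", seed = 5,
                              max_iter = 40))
  fb <- suppressWarnings(zifa(sim$Y, K = 3, method = "block",
                              block_size = 20, seed = 5, max_iter = 40))
  expect_equal(fb$loglik_trace, fe$loglik_trace, tolerance = 1e-10)
  expect_equal(fb$params$A, fe$params$A, tolerance = 1e-10)
})

test_that("block E-step cost grows roughly linearly in the gene count", {
  p400 <- rand_params(400, 4, lam = 0.1, seed = 33)
  y400 <- zifa_sample(p400, 40, seed = 34)$Y
  time_at <- function(D) {
    p <- zifa_params(p400$A[1:D, , drop = FALSE], p400$mu[1:D],
                     p400$sigma2[1:D], p400$lam)
    y <- y400[, 1:D, drop = FALSE]
    blocks <- make_gene_blocks(D, 50, seed = 1)
    system.time(for (r in 1:3) zifa_e_step(p, y, blocks = blocks))["elapsed"]
  }
  t100 <- time_at(100)
  t400 <- time_at(400)
  # quadratic growth would give a ratio of ~16; allow generous noise
  expect_lt(t400 / max(t100, 1e-3), 10)
})

test_that("fitted object exposes coherent methods", {
  sim <- simulate_factor_data(N = 50, D = 15, K = 2, sigma2 = 0.3,
                              lam = 0.1, seed = 35)
  f <- suppressWarnings(zifa(sim$Y, K = 2, seed = 1, max_iter = 50))
  expect_s3_class(f, "zifa")
  expect_output(print(f), "Zero-inflated factor analysis")
  expect_output(print(summary(f)), "zero fractions")
  expect_named(coef(f), c("A", "mu", "sigma2", "lam"))
  expect_equal(as.numeric(logLik(f)), f$loglik_trace[length(f$loglik_trace)])
  expect_equal(predict(f), f$Ez)
  expect_equal(dim(predict(f, sim$Y[1:5, ])), c(5, 2))
  expect_equal(fitted(f)[sim$Y != 0], sim$Y[sim$Y != 0])
  r <- residuals(f)
  expect_true(all(is.na(r[sim$Y == 0])))
  expect_equal(dim(simulate(f, nsim = 7, seed = 2)$Y), c(7, 15))
})
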