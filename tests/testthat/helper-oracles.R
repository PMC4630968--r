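# Independent oracles used across the suite.

# Moments of N(x; m, s2) * exp(-lam x^2) by adaptive quadrature.
quad_zi_moments <- function(m, s2, lam) {
  f <- function(x) dnorm(x, m, sqrt(s2)) * exp(-lam * x^2)
  mass <- integrate(f, -Inf, Inf, rel.tol = 1e-12, abs.tol = 0)$value
  mean_ <- integrate(function(x) x * f(x), -Inf, Inf,
                     rel.tol = 1e-12, abs.tol = 0)$value / mass
  second <- integrate(function(x) x^2 * f(x), -Inf, Inf,
                      rel.tol = 1e-12, abs.tol = 0)$value / mass
  list(mass = mass, mean = mean_, var = second - mean_^2)
}

# Importance-sampling posterior moments for one cell of a K = 1 model:
# draw (z, x_zero) from the prior-conditional, weight by the likelihood
# factors. Returns estimates and standard errors (ratio-estimator form).
is_cell_moments <- function(params, yi, n_draw = 1e6) {
  stopifnot(params$K == 1)
  z <- rnorm(n_draw)
  D <- params$D
  logw <- numeric(n_draw)
  xs <- list()
  for (j in seq_len(D)) {
    mj <- params$A[j, 1] * z + params$mu[j]
    if (yi[j] == 0) {
      xs[[as.character(j)]] <- rnorm(n_draw, mj, sqrt(params$sigma2[j]))
      logw <- logw - params$lam * xs[[as.character(j)]]^2
    } else {
      logw <- logw + dnorm(yi[j], mj, sqrt(params$sigma2[j]), log = TRUE)
    }
  }
  w <- exp(logw - max(logw))
  wn <- w / sum(w)
  est <- function(f) {
    mu <- sum(wn * f)
    list(est = mu, se = sqrt(sum(wn^2 * (f - mu)^2)))
  }
  zero_js <- which(yi == 0)
  out <- list(Ez = est(z), Ez2 = est(z^2))
  for (j in zero_js) {
    xj <- xs[[as.character(j)]]
    out[[paste0("Ex", j)]] <- est(xj)
    out[[paste0("Ex2_", j)]] <- est(xj^2)
    out[[paste0("Exz", j)]] <- est(xj * z)
  }
  out
}

# Small random parameter set for toy tests.
rand_params <- function(D, K, lam = 0.3, seed = 1) {
  set.seed(seed)
  zifa_params(matrix(runif(D * K, -0.5, 0.5), D, K),
              runif(D, 1, 2.5), runif(D, 0.2, 0.8), lam)
}

expect_within_3se <- function(value, oracle) {
  expect_lt(abs(value - oracle$est), 3 * oracle$se + 1e-10)
}
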