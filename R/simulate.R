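# Simulation framework. Factor-model data: loadings U(-0.5, 0.5), noise
# variances U(0.9, 1.1) * sigma2, gene means U(2.7, 3.3); latent positions
# standard normal. Dropout is applied by one of three mechanisms: the
# double-exponential law exp(-lam x^2) assumed by the model, a linear decay
# 1 - lam x (clipped to [0, 1]), or a missing-at-random per-gene rate
# (the latter two probe robustness to dropout-model misspecification).

draw_true_params <- function(D, K, sigma2) {
  A <- matrix(runif(D * K, -0.5, 0.5), D, K)
  s2 <- runif(D, 0.9, 1.1) * sigma2
  mu <- runif(D, 2.7, 3.3)
  zifa_params(A, mu, s2, lam = 1)  # lam placeholder; mechanism decides dropout
}

apply_dropout <- function(X, mechanism, lam, uniform_rates, clip_linear) {
  N <- nrow(X); D <- ncol(X)
  p0 <- switch(mechanism,
    double_exponential = exp(-lam * X^2),
    linear = {
      p <- 1 - lam * X
      if (!clip_linear && (any(p < 0) || any(p > 1)))
        stop("linear dropout probabilities fall outside [0, 1]; set clip_linear = TRUE")
      pmin(pmax(p, 0), 1)
    },
    uniform = matrix(uniform_rates, N, D, byrow = TRUE))
  H <- matrix(rbinom(N * D, 1, p0), N, D)
  list(H = H, Y = X * (1 - H))
}

#' Simulate factor-model data with dropouts
#'
#' Generates a synthetic log-expression matrix from the linear-Gaussian
#' factor model and masks entries with one of three dropout mechanisms.
#' Defaults reproduce the base simulation setting `N = 150`, `K = 10`,
#' `D = 50`, `sigma2 = 0.3`, `lam = 0.1`.
#'
#' @param N,D,K cells, genes, latent dimensions.
#' @param sigma2 base noise variance; per-gene variances are
#'   `U(0.9, 1.1) * sigma2`.
#' @param lam dropout decay (double-exponential) or slope (linear).
#' @param mechanism `"double_exponential"`, `"linear"` or `"uniform"`
#'   (missing at random).
#' @param uniform_rates per-gene dropout probabilities for
#'   `mechanism = "uniform"`; defaults to `U(0.1, 0.5)` draws.
#' @param clip_linear clip linear-decay probabilities into `[0, 1]`
#'   (default); with `FALSE`, out-of-range values are an error.
#' @param seed integer seed.
#' @return object of class `"zifa_sim"`: observed `Y`, pre-dropout `X`,
#'   latent `Z`, mask `H`, `true_params` ([zifa_params()]; its `lam` is the
#'   generating value for the double-exponential mechanism), and `config`.
#' @export
simulate_factor_data <- function(N = 150, D = 50, K = 10, sigma2 = 0.3,
                                 lam = 0.1,
                                 mechanism = c("double_exponential",
                                               "linear", "uniform"),
                                 uniform_rates = NULL, clip_linear = TRUE,
                                 seed = 1) {
  mechanism <- match.arg(mechanism)
  stopifnot(N >= 2, D >= 1, K >= 1, sigma2 > 0, lam > 0)
  with_seed(seed, {
    params <- draw_true_params(D, K, sigma2)
    if (mechanism == "double_exponential") params$lam <- lam
    if (mechanism == "uniform" && is.null(uniform_rates))
      uniform_rates <- runif(D, 0.1, 0.5)
    if (!is.null(uniform_rates) &&
        (any(uniform_rates < 0) || any(uniform_rates > 1)))
      stop("`uniform_rates` must lie in [0, 1]")
    Z <- matrix(rnorm(N * K), N, K)
    X <- Z %*% t(params$A) +
      matrix(params$mu, N, D, byrow = TRUE) +
      matrix(rnorm(N * D, sd = rep(sqrt(params$sigma2), each = N)), N, D)
    dr <- apply_dropout(X, mechanism, lam, uniform_rates, clip_linear)
    structure(list(Y = dr$Y, X = X, Z = Z, H = dr$H,
                   true_params = params, cluster_labels = NULL,
                   config = list(N = N, D = D, K = K, sigma2 = sigma2,
                                 lam = lam, mechanism = mechanism,
                                 uniform_rates = uniform_rates, seed = seed)),
              class = "zifa_sim")
  })
}

#' Simulate clustered data with dropouts
#'
#' Synthetic cell-type data for separability studies: cluster centers are
#' drawn in the latent space with a controlled separation, cells are
#' assigned uniformly to clusters with unit within-cluster spread, and the
#' factor-model projection plus a dropout mechanism produce the observed
#' matrix. Labels are returned for classifier-based evaluation.
#'
#' @inheritParams simulate_factor_data
#' @param n_clusters number of cell types (>= 2).
#' @param separation standard deviation of the cluster centers in latent
#'   space, in units of the within-cluster spread (1); larger values give
#'   better-separated types. Must be positive.
#' @return a `"zifa_sim"` whose `cluster_labels` is a length-N factor.
#' @export
simulate_cluster_scaffold <- function(N = 150, D = 500, K = 10,
                                      n_clusters = 3, separation = 2,
                                      sigma2 = 0.3, lam = 0.1,
                                      mechanism = c("double_exponential",
                                                    "linear", "uniform"),
                                      uniform_rates = NULL,
                                      clip_linear = TRUE, seed = 1) {
  mechanism <- match.arg(mechanism)
  stopifnot(n_clusters >= 2)
  if (separation <= 0) stop("`separation` must be positive")
  with_seed(seed, {
    params <- draw_true_params(D, K, sigma2)
    if (mechanism == "double_exponential") params$lam <- lam
    if (mechanism == "uniform" && is.null(uniform_rates))
      uniform_rates <- runif(D, 0.1, 0.5)
    centers <- matrix(rnorm(n_clusters * K, sd = separation), n_clusters, K)
    labels <- sample.int(n_clusters, N, replace = TRUE)
    Z <- centers[labels, , drop = FALSE] + matrix(rnorm(N * K), N, K)
    X <- Z %*% t(params$A) +
      matrix(params$mu, N, D, byrow = TRUE) +
      matrix(rnorm(N * D, sd = rep(sqrt(params$sigma2), each = N)), N, D)
    dr <- apply_dropout(X, mechanism, lam, uniform_rates, clip_linear)
    structure(list(Y = dr$Y, X = X, Z = Z, H = dr$H,
                   true_params = params,
                   cluster_labels = factor(labels),
                   config = list(N = N, D = D, K = K, sigma2 = sigma2,
                                 lam = lam, mechanism = mechanism,
                                 n_clusters = n_clusters,
                                 separation = separation, seed = seed)),
              class = "zifa_sim")
  })
}

#' @export
print.zifa_sim <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("Simulated zero-inflated data: N = %d cells, D = %d genes, K = %d\n",
              cfg$N, cfg$D, cfg$K))
  cat(sprintf("  mechanism = %s, dropout fraction = %.3f\n",
              cfg$mechanism, mean(x$H)))
  if (!is.null(x$cluster_labels))
    cat(sprintf("  %d clusters, separation = %.2f\n",
                cfg$n_clusters, cfg$separation))
  invisible(x)
}
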