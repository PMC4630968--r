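# Generative model: z ~ N(0, I_K); x | z ~ N(A z + mu, diag(sigma2));
# h_j | x_j ~ Bernoulli(exp(-lam * x_j^2)); y_j = x_j unless h_j = 1, then 0.
# Parameters Theta = (A, mu, sigma2, lam) with lam shared across genes.

#' Dropout probability under the double-exponential model
#'
#' Probability that a latent log-expression value `x` is replaced by an
#' observed zero: `exp(-lam * x^2)`. Strongly expressed genes almost never
#' drop out; values near zero almost always do.
#'
#' @param x latent log-expression value(s).
#' @param lam positive decay parameter, shared across genes.
#' @return probabilities in `(0, 1]`, recycled over `x`.
#' @examples
#' dropout_prob(0, 0.1)   # 1
#' dropout_prob(3, 0.1)   # exp(-0.9)
#' @export
dropout_prob <- function(x, lam) {
  stopifnot(is.numeric(x), is.numeric(lam), all(lam > 0))
  exp(-lam * x^2)
}

#' Moments of a Gaussian density tilted by exp(-lam * x^2)
#'
#' For the unnormalized density `N(x; m, s2) * exp(-lam * x^2)` returns the
#' normalizing mass, and the mean and variance of the normalized density.
#' This is the identity that makes the E-step closed form: a zero entry
#' contributes a Gaussian factor in `m` with variance inflated to
#' `s2 + 1/(2 lam)`, and conditional on the latent position the hidden
#' expression is Gaussian with mean `m / (1 + 2 lam s2)` and variance
#' `s2 / (1 + 2 lam s2)`.
#'
#' @param m mean of the untilted Gaussian (vectorized).
#' @param s2 positive variance of the untilted Gaussian (vectorized).
#' @param lam nonnegative decay parameter; `lam = 0` is the untilted limit.
#' @return list with components `mass`, `mean`, `var` (vectors).
#' @export
zi_gauss_moments <- function(m, s2, lam) {
  if (any(s2 <= 0)) stop("`s2` must be positive")
  if (any(lam < 0)) stop("`lam` must be nonnegative")
  denom <- 1 + 2 * lam * s2
  list(
    mass = denom^(-0.5) * exp(-lam * m^2 / denom),
    mean = m / denom,
    var  = s2 / denom
  )
}

#' Construct a ZIFA parameter set
#'
#' @param A D x K loadings matrix.
#' @param mu length-D vector of gene means (log-counts).
#' @param sigma2 length-D vector of positive per-gene noise variances.
#' @param lam positive dropout decay parameter.
#' @return object of class `"zifa_params"`.
#' @export
zifa_params <- function(A, mu, sigma2, lam) {
  A <- as.matrix(A)
  D <- nrow(A); K <- ncol(A)
  stopifnot(length(mu) == D, length(sigma2) == D, K >= 1, K <= D)
  if (any(sigma2 <= 0)) stop("`sigma2` must be positive")
  if (length(lam) != 1 || lam <= 0) stop("`lam` must be a positive scalar")
  structure(list(A = A, mu = as.numeric(mu), sigma2 = as.numeric(sigma2),
                 lam = lam, K = K, D = D),
            class = "zifa_params")
}

#' @export
print.zifa_params <- function(x, ...) {
  cat(sprintf("ZIFA parameters: D = %d genes, K = %d latent dimensions\n",
              x$D, x$K))
  cat(sprintf("  lambda = %.4g; sigma2 in [%.4g, %.4g]; mu in [%.4g, %.4g]\n",
              x$lam, min(x$sigma2), max(x$sigma2), min(x$mu), max(x$mu)))
  invisible(x)
}

#' Draw cells from the ZIFA generative model
#'
#' Samples latent positions, pre-dropout expression, the dropout mask and
#' the observed zero-inflated matrix for `n_cells` independent cells.
#'
#' @param params a [zifa_params()] object.
#' @param n_cells number of cells to draw.
#' @param seed optional integer seed (RNG state is restored afterwards).
#' @return list of class `"zifa_sample"` with `Z` (N x K), `X` (N x D),
#'   `H` (N x D binary dropout mask) and `Y` (N x D observed).
#' @export
zifa_sample <- function(params, n_cells, seed = NULL) {
  stopifnot(inherits(params, "zifa_params"), n_cells >= 1)
  with_seed(seed, {
    D <- params$D; K <- params$K
    Z <- matrix(rnorm(n_cells * K), n_cells, K)
    X <- Z %*% t(params$A) +
      matrix(params$mu, n_cells, D, byrow = TRUE) +
      matrix(rnorm(n_cells * D, sd = rep(sqrt(params$sigma2), each = n_cells)),
             n_cells, D)
    H <- matrix(rbinom(n_cells * D, 1, dropout_prob(X, params$lam)),
                n_cells, D)
    Y <- X * (1 - H)
    structure(list(Z = Z, X = X, H = H, Y = Y), class = "zifa_sample")
  })
}

#' Observed-data log-likelihood of a ZIFA parameter set
#'
#' Exact log p(Y | Theta), marginalizing the latent position and the hidden
#' expression at zero entries in closed form. Zero entries are identified
#' with dropouts (an exact continuous value of 0 has probability zero), so
#' each contributes a Gaussian factor with variance inflated by `1/(2 lam)`
#' times the tilt mass; nonzero entries contribute their Gaussian density
#' times the non-dropout probability `1 - exp(-lam y^2)`.
#'
#' @param params a [zifa_params()] object.
#' @param y N x D matrix of log-expression, cells in rows.
#' @return scalar log-likelihood.
#' @export
zifa_loglik <- function(params, y) {
  stopifnot(inherits(params, "zifa_params"))
  check_matrix(y)
  if (ncol(y) != params$D)
    stop(sprintf("`y` has %d genes but `params` expects %d", ncol(y), params$D))
  A <- params$A; mu <- params$mu; s2 <- params$sigma2; lam <- params$lam
  K <- params$K
  inflate <- 1 / (2 * lam)
  total <- 0
  for (i in seq_len(nrow(y))) {
    yi <- y[i, ]
    zero <- yi == 0
    tau2 <- ifelse(zero, s2 + inflate, s2)
    u <- ifelse(zero, 0, yi) - mu
    # marginal over z: N(v; mu, A A' + diag(tau2)) via Woodbury
    Ai <- A / sqrt(tau2)
    P <- diag(K) + crossprod(Ai)           # I + A' D^-1 A
    r <- crossprod(A, u / tau2)
    ch <- chol(P)
    w <- backsolve(ch, forwardsolve(t(ch), r))
    quad <- sum(u^2 / tau2) - sum(r * w)
    logdet <- sum(log(tau2)) + 2 * sum(log(diag(ch)))
    ll <- -0.5 * (length(yi) * log(2 * pi) + logdet + quad)
    nz <- yi[!zero]
    ll <- ll + sum(log1mexp(lam * nz^2)) + sum(zero) * 0.5 * log(pi / lam)
    total <- total + ll
  }
  total
}
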