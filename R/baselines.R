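# Reference linear embeddings: PCA (prcomp), probabilistic PCA via the
# closed-form eigendecomposition solution, and factor analysis via a small
# EM on the covariance scale. FA/PPCA are fitted here rather than through
# stats::factanal because the evaluation module needs covariance-scale
# generative fits it can draw posterior-predictive samples from; factanal
# works on correlation matrices with rotation conventions and offers no
# such object. None of these model dropout: their predictive law is purely
# Gaussian, which is exactly the mismatch the predictive checks expose.

new_linear_embedding <- function(method, loadings, means, noise, Z_hat,
                                 converged = TRUE) {
  structure(list(method = method, loadings = loadings, means = means,
                 noise = noise, Z_hat = Z_hat, converged = converged,
                 K = ncol(loadings), D = nrow(loadings)),
            class = "linear_embedding")
}

#' @export
print.linear_embedding <- function(x, ...) {
  cat(sprintf("%s embedding: D = %d genes -> K = %d dimensions (N = %d cells)\n",
              toupper(x$method), x$D, x$K, nrow(x$Z_hat)))
  invisible(x)
}

#' Principal components embedding
#'
#' Top-`K` principal directions of the column-centered matrix and the
#' projections of the cells onto them.
#'
#' @param y cells-by-genes matrix.
#' @param K number of components, `K <= min(N - 1, D)`.
#' @return a `"linear_embedding"` with orthonormal `loadings` (D x K),
#'   column `means`, residual `noise` variance per gene, and `Z_hat`
#'   (N x K scores).
#' @export
fit_pca <- function(y, K) {
  check_matrix(y)
  if (K > min(nrow(y) - 1, ncol(y)))
    stop("`K` must be at most min(N - 1, D)")
  pc <- prcomp(y, center = TRUE, scale. = FALSE)
  W <- pc$rotation[, seq_len(K), drop = FALSE]
  Z <- pc$x[, seq_len(K), drop = FALSE]
  resid <- y - Z %*% t(W) - matrix(pc$center, nrow(y), ncol(y), byrow = TRUE)
  new_linear_embedding("pca", W, pc$center, apply(resid, 2, var), Z)
}

#' Probabilistic PCA fit
#'
#' Maximum-likelihood PPCA (isotropic Gaussian noise shared across genes)
#' by the closed-form eigendecomposition solution: the noise variance is
#' the mean of the discarded eigenvalues and the loadings are the leading
#' eigenvectors scaled by `sqrt(eigenvalue - noise)`. `Z_hat` holds the
#' posterior mean latent positions.
#'
#' @inheritParams fit_pca
#' @return a `"linear_embedding"`; `noise` is a positive scalar.
#' @export
fit_ppca <- function(y, K) {
  check_matrix(y)
  N <- nrow(y); D <- ncol(y)
  if (K > min(N - 1, D)) stop("`K` must be at most min(N - 1, D)")
  mu <- colMeans(y)
  S <- cov(y)
  eig <- eigen(S, symmetric = TRUE)
  ev <- pmax(eig$values, 0)
  noise <- if (K < D) max(mean(ev[(K + 1):D]), 1e-8) else 1e-8
  scale <- sqrt(pmax(ev[seq_len(K)] - noise, 1e-8))
  W <- eig$vectors[, seq_len(K), drop = FALSE] %*% diag(scale, K)
  Z <- ppca_scores(y, W, mu, rep(noise, D))
  new_linear_embedding("ppca", W, mu, noise, Z)
}

# Posterior mean E[z | y] for a Gaussian factor model with loadings W,
# means mu and per-gene noise psi: (I + W' Psi^-1 W)^-1 W' Psi^-1 (y - mu).
ppca_scores <- function(y, W, mu, psi) {
  Ws <- W / psi
  M <- diag(ncol(W)) + crossprod(Ws, W)
  t(solve(M, crossprod(Ws, t(y) - mu)))
}

#' Factor analysis fit
#'
#' Maximum-likelihood factor analysis (per-gene diagonal Gaussian noise) by
#' EM on the covariance scale, initialized from the PPCA solution. `Z_hat`
#' holds the posterior mean latent positions.
#'
#' @inheritParams fit_pca
#' @param max_iter,tol EM iteration cap and convergence threshold on the
#'   change in per-entry log-likelihood.
#' @return a `"linear_embedding"`; `noise` is a length-D vector. If the
#'   iteration cap is reached, `converged` is `FALSE`.
#' @export
fit_fa <- function(y, K, max_iter = 500, tol = 1e-8) {
  check_matrix(y)
  N <- nrow(y); D <- ncol(y)
  if (K > min(N - 1, D)) stop("`K` must be at most min(N - 1, D)")
  mu <- colMeans(y)
  yc <- sweep(y, 2, mu)
  S <- crossprod(yc) / N
  pp <- fit_ppca(y, K)
  W <- pp$loadings
  psi <- pmax(diag(S) - rowSums(W^2), 1e-6)
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    Ws <- W / psi
    M <- diag(K) + crossprod(Ws, W)          # posterior precision of z
    Minv <- chol2inv(chol(M))
    B <- yc %*% Ws %*% Minv                  # E[z | y], N x K
    Szz <- N * Minv + crossprod(B)
    Syz <- crossprod(yc, B)
    W <- t(solve(Szz, t(Syz)))
    psi <- pmax(diag(S) - rowSums(W * Syz) / N, 1e-6)
    ll <- fa_loglik(S, W, psi, N)
    if (abs(ll - ll_old) / (N * D) < tol) { converged <- TRUE; break }
    ll_old <- ll
  }
  Z <- ppca_scores(y, W, mu, psi)
  new_linear_embedding("fa", W, mu, psi, Z, converged = converged)
}

# Gaussian log-likelihood of a sample covariance S under Sigma = WW' + Psi.
fa_loglik <- function(S, W, psi, N) {
  D <- nrow(S); K <- ncol(W)
  Ws <- W / psi
  M <- diag(K) + crossprod(Ws, W)
  ch <- chol(M)
  logdet <- sum(log(psi)) + 2 * sum(log(diag(ch)))
  # tr(Sigma^-1 S) via Woodbury
  tr <- sum(diag(S) / psi) -
    sum(diag(chol2inv(ch) %*% crossprod(Ws, S %*% Ws)))
  -0.5 * N * (D * log(2 * pi) + logdet + tr)
}

#' Embed new cells with a fitted linear model
#'
#' @param object a `"linear_embedding"`.
#' @param newdata cells-by-genes matrix with the same genes; defaults to
#'   returning the stored `Z_hat`.
#' @param ... unused.
#' @return N x K matrix of latent coordinates.
#' @export
predict.linear_embedding <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$Z_hat)
  check_matrix(newdata)
  if (ncol(newdata) != object$D) stop("gene dimension mismatch")
  if (object$method == "pca") {
    sweep(newdata, 2, object$means) %*% object$loadings
  } else {
    psi <- if (length(object$noise) == 1) rep(object$noise, object$D)
           else object$noise
    ppca_scores(newdata, object$loadings, object$means, psi)
  }
}

#' Draw from the generative law of a fitted linear embedding
#'
#' Samples synthetic cells from the fitted Gaussian factor model
#' (`z ~ N(0, I)`, `y = W z + mu + noise`). There is no dropout stage:
#' these draws are the posterior-predictive distribution the model itself
#' believes in.
#'
#' @param object a `"linear_embedding"` (PPCA or FA; PCA has no generative
#'   law and is rejected).
#' @param nsim number of cells to draw.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return `nsim` x D matrix.
#' @export
simulate.linear_embedding <- function(object, nsim = 1, seed = NULL, ...) {
  if (object$method == "pca")
    stop("PCA has no probabilistic generative law; use fit_ppca or fit_fa")
  psi <- if (length(object$noise) == 1) rep(object$noise, object$D)
         else object$noise
  with_seed(seed, {
    Z <- matrix(rnorm(nsim * object$K), nsim, object$K)
    Z %*% t(object$loadings) +
      matrix(object$means, nsim, object$D, byrow = TRUE) +
      matrix(rnorm(nsim * object$D, sd = rep(sqrt(psi), each = nsim)),
             nsim, object$D)
  })
}
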