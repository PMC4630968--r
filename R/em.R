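# EM for ZIFA. Conditioning on z, genes are independent; a zero entry's
# exp(-lam x^2)-tilted Gaussian factor collapses (zi_gauss_moments) to a
# pseudo-observation of 0 with variance sigma2_j + 1/(2 lam), so the E-step
# posterior over (z, hidden x at zeros) is jointly Gaussian and closed form.
# The block variant computes these moments within disjoint gene blocks,
# which keeps the cost linear in the number of genes.

#' Partition genes into random blocks
#'
#' Randomly permutes gene indices and chunks them into consecutive blocks
#' of `block_size` (the last block may be smaller). Used by the
#' block-approximate EM.
#'
#' @param D number of genes.
#' @param block_size target genes per block, in `[1, D]`.
#' @param seed optional integer seed.
#' @return list of disjoint integer vectors covering `1:D`.
#' @export
make_gene_blocks <- function(D, block_size, seed = NULL) {
  stopifnot(block_size >= 1, block_size <= D)
  with_seed(seed, {
    perm <- sample.int(D)
    unname(split(perm, ceiling(seq_along(perm) / block_size)))
  })
}

#' Initialize ZIFA parameters
#'
#' Means from column means; loadings and noise from a probabilistic-PCA
#' eigendecomposition treating zeros as observed values; `lam` from a
#' least-squares fit of the per-gene zero fraction against
#' `exp(-lam * m_j^2)`, where `m_j` is the gene's mean nonzero expression
#' (the empirical dropout-vs-mean-expression relationship). On a zero-free
#' matrix `lam` falls back to 0.05, since the regression carries no signal.
#'
#' @param y cells-by-genes matrix.
#' @param K latent dimensionality.
#' @param seed optional integer seed (initialization is deterministic; kept
#'   for interface symmetry).
#' @return a [zifa_params()] object.
#' @export
zifa_init <- function(y, K, seed = NULL) {
  check_matrix(y)
  N <- nrow(y); D <- ncol(y)
  stopifnot(K >= 1, K <= D, K <= N - 1)
  nzero_per_gene <- colSums(y != 0)
  if (any(nzero_per_gene == 0))
    stop("some genes have no nonzero entries; filter them out before fitting (filter_genes)")
  mu <- colMeans(y)
  pp <- fit_ppca(y, K)
  sigma2 <- pmax(apply(y, 2, var) - rowSums(pp$loadings^2), 1e-6)
  p0 <- colMeans(y == 0)
  if (all(p0 == 0)) {
    lam <- 0.05
  } else {
    mnz <- vapply(seq_len(D), function(j) mean(y[y[, j] != 0, j]), numeric(1))
    obj <- function(l) sum((p0 - exp(-l * mnz^2))^2)
    # the objective is flat for large lam, which defeats golden-section
    # search on the full interval; scan a log grid first, then refine
    grid <- 10^seq(-4, log10(20), length.out = 60)
    best <- which.min(vapply(grid, obj, numeric(1)))
    lo <- grid[max(best - 1, 1)]
    hi <- grid[min(best + 1, length(grid))]
    lam <- optimize(obj, c(lo, hi))$minimum
  }
  zifa_params(pp$loadings, mu, sigma2, lam)
}

# Per-cell, per-block Gaussian posterior over z plus the tilted-Gaussian
# moments of hidden x at zero entries. Returns the LatentPosterior bundle.
e_step_impl <- function(params, y, blocks) {
  A <- params$A; mu <- params$mu; s2 <- params$sigma2; lam <- params$lam
  K <- params$K; D <- params$D
  N <- nrow(y)
  inflate <- 1 / (2 * lam)
  cshrink <- 1 / (1 + 2 * lam * s2)          # per-gene tilt shrinkage
  nb <- length(blocks)
  Ez <- matrix(0, N, K)
  Vz <- array(0, c(K, K, N))
  EX <- y
  EX2 <- y^2
  EXZ <- array(0, c(N, D, K))
  bEz <- lapply(seq_len(nb), function(b) matrix(0, N, K))
  bVz <- lapply(seq_len(nb), function(b) array(0, c(K, K, N)))
  zero <- y == 0
  for (i in seq_len(N)) {
    Ppool <- diag(K)
    rpool <- numeric(K)
    for (b in seq_len(nb)) {
      J <- blocks[[b]]
      aJ <- A[J, , drop = FALSE]
      zJ <- zero[i, J]
      tau2 <- ifelse(zJ, s2[J] + inflate, s2[J])
      u <- ifelse(zJ, 0, y[i, J]) - mu[J]
      As <- aJ / tau2
      P <- diag(K) + crossprod(As, aJ)
      r <- crossprod(As, u)
      ch <- tryCatch(chol(P), error = function(e)
        stop("singular posterior precision in E-step; consider filtering very sparse genes"))
      C <- chol2inv(ch)
      bmean <- drop(C %*% r)
      bEz[[b]][i, ] <- bmean
      bVz[[b]][, , i] <- C
      Ppool <- Ppool + (P - diag(K))
      rpool <- rpool + r
      Ezz <- C + tcrossprod(bmean)
      obsJ <- J[!zJ]
      if (length(obsJ) > 0)
        EXZ[i, obsJ, ] <- y[i, obsJ] %o% bmean
      zeroJ <- J[zJ]
      if (length(zeroJ) > 0) {
        az <- A[zeroJ, , drop = FALSE]
        cz <- cshrink[zeroJ]
        muz <- mu[zeroJ]
        proj <- drop(az %*% bmean)            # a_j' E[z]
        azE <- az %*% Ezz                     # rows a_j' E[zz']
        EX[i, zeroJ] <- cz * (proj + muz)
        EX2[i, zeroJ] <- cz * s2[zeroJ] +
          cz^2 * (rowSums(azE * az) + 2 * muz * proj + muz^2)
        EXZ[i, zeroJ, ] <- cz * (azE + muz %o% bmean)
      }
    }
    chp <- chol(Ppool)
    Cp <- chol2inv(chp)
    Ez[i, ] <- drop(Cp %*% rpool)
    Vz[, , i] <- Cp
  }
  structure(list(Ez = Ez, Vz = Vz, EX = EX, EX2 = EX2, EXZ = EXZ,
                 blocks = blocks, bEz = bEz, bVz = bVz, zero = zero),
            class = "zifa_posterior")
}

#' E-step: posterior moments of the latent state
#'
#' Computes, for each cell, the Gaussian posterior over the latent position
#' `z` and the moments of the hidden expression at zero entries, given
#' parameters. With `blocks = NULL` (or a single block) the computation is
#' exact; with a partition it is exact within each block, and the per-cell
#' z-moments are pooled across blocks by precision weighting with the prior
#' counted once.
#'
#' @param params a [zifa_params()] object.
#' @param y cells-by-genes matrix.
#' @param blocks optional list of gene-index blocks from
#'   [make_gene_blocks()].
#' @return object of class `"zifa_posterior"`: `Ez` (N x K), `Vz`
#'   (K x K x N), `EX`/`EX2` (N x D moments of x, equal to `y`/`y^2` at
#'   observed entries), `EXZ` (N x D x K cross-moments), plus the per-block
#'   moments.
#' @export
zifa_e_step <- function(params, y, blocks = NULL) {
  stopifnot(inherits(params, "zifa_params"))
  check_matrix(y)
  if (ncol(y) != params$D) stop("dimension mismatch between `params` and `y`")
  if (is.null(blocks)) blocks <- list(seq_len(ncol(y)))
  e_step_impl(params, y, blocks)
}

# Expected complete-data log-likelihood (up to the constant z-prior entropy
# terms that do not involve parameters). Used to verify M-step ascent.
expected_complete_loglik <- function(params, post, y) {
  A <- params$A; mu <- params$mu; s2 <- params$sigma2; lam <- params$lam
  N <- nrow(y)
  total <- -0.5 * N * sum(log(2 * pi * s2))
  for (b in seq_along(post$blocks)) {
    J <- post$blocks[[b]]
    Szz <- apply(post$bVz[[b]], c(1, 2), sum) + crossprod(post$bEz[[b]])
    for (j in J) {
      aj <- A[j, ]
      Sxz <- colSums(matrix(post$EXZ[, j, ], nrow = N))
      quad <- sum(post$EX2[, j]) - 2 * sum(aj * Sxz) -
        2 * mu[j] * sum(post$EX[, j]) +
        drop(aj %*% Szz %*% aj) +
        2 * mu[j] * sum(post$bEz[[b]] %*% aj) + N * mu[j]^2
      total <- total - quad / (2 * s2[j])
    }
  }
  zmask <- post$zero
  total <- total - lam * sum(post$EX2[zmask])
  ynz <- y[!zmask]
  total + sum(log1mexp(lam * ynz^2))
}

#' M-step: maximize the expected complete log-likelihood
#'
#' Updates loadings, means and noise variances by per-gene linear systems in
#' the E-step sufficient statistics, and the dropout decay `lam` by bounded
#' one-dimensional maximization of its expected terms, including the
#' `log(1 - exp(-lam y^2))` contribution of observed nonzero entries.
#'
#' @param post a `"zifa_posterior"` from [zifa_e_step()].
#' @param y cells-by-genes matrix (same zero pattern the posterior was
#'   computed from).
#' @param prev previous [zifa_params()] (used for dimensions and as the
#'   `lam` fallback if the one-dimensional search cannot improve on it).
#' @param tied_variance if `TRUE`, a single noise variance shared by all
#'   genes is fitted (the zero-inflated analogue of probabilistic PCA).
#' @return updated [zifa_params()].
#' @export
zifa_m_step <- function(post, y, prev, tied_variance = FALSE) {
  stopifnot(inherits(post, "zifa_posterior"), inherits(prev, "zifa_params"))
  N <- nrow(y); D <- ncol(y); K <- prev$K
  A <- matrix(0, D, K)
  mu <- numeric(D)
  sigma2 <- numeric(D)
  S1 <- colSums(post$EX)
  Sxx <- colSums(post$EX2)
  for (b in seq_along(post$blocks)) {
    J <- post$blocks[[b]]
    Eb <- post$bEz[[b]]
    Szz <- apply(post$bVz[[b]], c(1, 2), sum) + crossprod(Eb)
    Sz <- colSums(Eb)
    G <- rbind(cbind(Szz, Sz), c(Sz, N))
    Sxz <- apply(post$EXZ[, J, , drop = FALSE], c(2, 3), sum)  # |J| x K
    rhs <- cbind(Sxz, S1[J])                                   # |J| x (K+1)
    B <- t(solve(G, t(rhs)))
    A[J, ] <- B[, seq_len(K), drop = FALSE]
    mu[J] <- B[, K + 1]
    for (idx in seq_along(J)) {
      j <- J[idx]
      aj <- A[j, ]
      quad <- Sxx[j] - 2 * sum(aj * Sxz[idx, ]) - 2 * mu[j] * S1[j] +
        drop(aj %*% Szz %*% aj) + 2 * mu[j] * sum(Sz * aj) + N * mu[j]^2
      sigma2[j] <- max(quad / N, 1e-6)
    }
  }
  if (tied_variance) sigma2 <- rep(mean(sigma2), D)
  # lam maximizes -lam * sum E[x^2 | dropout] + sum log(1 - exp(-lam y^2))
  zmask <- post$zero
  Szero <- sum(post$EX2[zmask])
  ynz2 <- y[!zmask]^2
  g <- function(l) -l * Szero + sum(log1mexp(l * ynz2))
  opt <- tryCatch(optimize(g, c(1e-8, 20), maximum = TRUE, tol = 1e-10),
                  error = function(e)
                    stop(sprintf("lam optimization failed on [1e-8, 20]: %s",
                                 conditionMessage(e))))
  lam <- if (g(opt$maximum) >= g(prev$lam)) opt$maximum else prev$lam
  zifa_params(A, mu, sigma2, lam)
}

#' Fit zero-inflated factor analysis
#'
#' Fits the ZIFA model to a cells-by-genes matrix of log read counts by EM,
#' treating exact zeros as candidate dropout events with probability
#' `exp(-lam * x^2)` given the latent expression `x`. `method = "exact"`
#' computes E-step moments from all genes jointly; `method = "block"`
#' (default) computes them within random disjoint gene blocks, which scales
#' linearly in the number of genes and closely tracks the exact moments.
#'
#' @param y cells-by-genes numeric matrix of log read counts (use
#'   [read_expression()] / [filter_genes()] to prepare it). Genes that are
#'   zero in every cell must be removed first.
#' @param K number of latent dimensions.
#' @param method `"block"` or `"exact"`.
#' @param block_size genes per block for `method = "block"`.
#' @param tied_variance fit a single shared noise variance (ZI-PPCA).
#' @param max_iter maximum EM iterations.
#' @param tol convergence threshold on the change in per-entry observed
#'   log-likelihood.
#' @param seed integer seed controlling initialization and the block
#'   permutation.
#' @param verbose print the log-likelihood trace while fitting.
#' @return object of class `"zifa"`: `params` ([zifa_params()]), `Ez`
#'   (N x K latent positions), `Vz`, imputed moments `EX`/`EX2`, the
#'   `loglik_trace`, `converged` flag, `iterations`, the block partition
#'   used, and the data.
#' @examples
#' sim <- simulate_factor_data(N = 60, D = 20, K = 2, sigma2 = 0.3,
#'                             lam = 0.1, seed = 1)
#' fit <- zifa(sim$Y, K = 2, seed = 1)
#' fit
#' @export
zifa <- function(y, K, method = c("block", "exact"), block_size = 50,
                 tied_variance = FALSE, max_iter = 200, tol = 1e-6,
                 seed = 1, verbose = FALSE) {
  method <- match.arg(method)
  check_matrix(y)
  N <- nrow(y); D <- ncol(y)
  stopifnot(K >= 1, K <= D)
  if (any(colSums(y != 0) == 0))
    stop("genes with all-zero columns cannot be fitted; remove them with filter_genes()")
  blocks <- if (method == "exact" || block_size >= D) list(seq_len(D))
            else make_gene_blocks(D, block_size, seed = seed)
  params <- zifa_init(y, K, seed = seed)
  trace <- zifa_loglik(params, y)
  converged <- FALSE
  post <- NULL
  iter <- 0
  while (iter < max_iter) {
    iter <- iter + 1
    post <- e_step_impl(params, y, blocks)
    params <- zifa_m_step(post, y, params, tied_variance = tied_variance)
    ll <- zifa_loglik(params, y)
    trace <- c(trace, ll)
    if (verbose)
      message(sprintf("iter %3d  loglik %.6f", iter, ll))
    if (abs(ll - trace[iter]) / (N * D) < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged)
    warning(sprintf("EM did not converge in %d iterations", max_iter))
  # Reported moments come from one exact E-step at the fitted parameters:
  # a single pass is linear in D anyway, so the block approximation is only
  # needed inside the iteration.
  post <- e_step_impl(params, y, list(seq_len(D)))
  structure(list(params = params, Ez = post$Ez, Vz = post$Vz,
                 EX = post$EX, EX2 = post$EX2,
                 loglik_trace = trace, converged = converged,
                 iterations = iter, method = method,
                 block_size = if (method == "block") block_size else D,
                 blocks = blocks, K = K, N = N, D = D,
                 tied_variance = tied_variance, y = y, seed = seed,
                 call = match.call()),
            class = "zifa")
}
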