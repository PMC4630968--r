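# Methods for fitted "zifa" objects.

#' @export
print.zifa <- function(x, ...) {
  cat(sprintf("Zero-inflated factor analysis fit (%s EM%s)\n",
              x$method, if (x$tied_variance) ", tied variance" else ""))
  cat(sprintf("  N = %d cells, D = %d genes, K = %d latent dimensions\n",
              x$N, x$D, x$K))
  cat(sprintf("  lambda = %.4g, dropout fraction = %.3f\n",
              x$params$lam, mean(x$y == 0)))
  cat(sprintf("  log-likelihood %.2f after %d iterations (%s)\n",
              x$loglik_trace[length(x$loglik_trace)], x$iterations,
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}

#' @export
summary.zifa <- function(object, ...) {
  s <- list(fit = object,
            sigma2_summary = summary(object$params$sigma2),
            zero_fraction = colMeans(object$y == 0),
            imputed_mean = mean(object$EX[object$y == 0]))
  class(s) <- "summary.zifa"
  s
}

#' @export
print.summary.zifa <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  gene zero fractions: median %.3f, max %.3f\n",
              median(x$zero_fraction), max(x$zero_fraction)))
  cat("  noise variances:\n")
  print(x$sigma2_summary)
  cat(sprintf("  mean imputed expression at zero entries: %.3f\n",
              x$imputed_mean))
  invisible(x)
}

#' @export
coef.zifa <- function(object, ...) {
  with(object$params, list(A = A, mu = mu, sigma2 = sigma2, lam = lam))
}

#' @export
logLik.zifa <- function(object, ...) {
  ll <- object$loglik_trace[length(object$loglik_trace)]
  attr(ll, "df") <- with(object$params, D * K + 2 * D + 1)
  attr(ll, "nobs") <- object$N
  class(ll) <- "logLik"
  ll
}

#' Latent positions for new cells
#'
#' Runs the (exact) E-step at the fitted parameters and returns posterior
#' mean latent coordinates. With no `newdata`, the training-cell positions
#' are returned.
#'
#' @param object a fitted [zifa()] object.
#' @param newdata optional cells-by-genes matrix over the same genes.
#' @param ... unused.
#' @return N x K matrix.
#' @export
predict.zifa <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$Ez)
  check_matrix(newdata)
  zifa_e_step(object$params, newdata)$Ez
}

#' @export
fitted.zifa <- function(object, ...) object$EX

#' @export
residuals.zifa <- function(object, ...) {
  r <- object$y - object$EX
  r[object$y == 0] <- NA_real_  # zeros are imputed, not observed
  r
}

#' Posterior-predictive draws from a fitted ZIFA model
#'
#' Samples synthetic cells from the fitted generative law, including the
#' dropout stage — so the draws are zero-inflated exactly as the model
#' believes the data to be.
#'
#' @param object a fitted [zifa()] object.
#' @param nsim number of cells to draw.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return a `"zifa_sample"` list with `Z`, `X`, `H`, `Y`.
#' @export
simulate.zifa <- function(object, nsim = 1, seed = NULL, ...) {
  zifa_sample(object$params, n_cells = nsim, seed = seed)
}

#' Plot the first two latent dimensions of a fit
#'
#' @param x a fitted [zifa()] object with `K >= 2`.
#' @param dims which two latent dimensions to show.
#' @param col point colors (e.g. cluster labels).
#' @param ... passed to [graphics::plot()].
#' @export
plot.zifa <- function(x, dims = c(1, 2), col = 1, ...) {
  stopifnot(length(dims) == 2, max(dims) <= x$K)
  graphics::plot(x$Ez[, dims[1]], x$Ez[, dims[2]],
                 xlab = sprintf("latent dim %d", dims[1]),
                 ylab = sprintf("latent dim %d", dims[2]),
                 col = col, ...)
  invisible(x)
}

#' Write / read ZIFA parameters as JSON
#'
#' Serializes a parameter set to a single JSON document (loadings row-major
#' as nested arrays) for command-line round-tripping.
#'
#' @param params a [zifa_params()] object.
#' @param path JSON file path.
#' @return `write_zifa_params` returns `path` invisibly; `read_zifa_params`
#'   returns a [zifa_params()] object.
#' @export
write_zifa_params <- function(params, path) {
  stopifnot(inherits(params, "zifa_params"))
  jsonlite::write_json(list(A = params$A, mu = params$mu,
                            sigma2 = params$sigma2, lam = params$lam,
                            K = params$K),
                       path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_zifa_params
#' @export
read_zifa_params <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  zifa_params(o$A, o$mu, o$sigma2, o$lam)
}
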