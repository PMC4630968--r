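# Internal helpers shared across the package.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's state afterwards so library code never clobbers user RNG.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  expr
}

# log(1 - exp(-t)) for t > 0, stable for both small and large t.
log1mexp <- function(t) {
  out <- numeric(length(t))
  small <- t <= log(2)
  out[small] <- log(-expm1(-t[small]))
  out[!small] <- log1p(-exp(-t[!small]))
  out
}

check_matrix <- function(y, name = "y") {
  if (!is.matrix(y) || !is.numeric(y))
    stop(sprintf("`%s` must be a numeric matrix (cells in rows, genes in columns)", name))
  if (any(!is.finite(y)))
    stop(sprintf("`%s` contains non-finite values", name))
  invisible(y)
}

#' Largest principal angle between two column spans
#'
#' Rotation-invariant comparison of loading matrices: the largest principal
#' angle (in radians) between the subspaces spanned by the columns of `a`
#' and `b`. Zero means identical spans.
#'
#' @param a,b numeric matrices with the same number of rows.
#' @return angle in radians, in `[0, pi/2]`.
#' @export
subspace_angle <- function(a, b) {
  qa <- qr.Q(qr(a))
  qb <- qr.Q(qr(b))
  s <- svd(crossprod(qa, qb))$d
  acos(max(-1, min(1, min(s))))
}
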