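# Evaluation procedures: Spearman agreement between true and estimated
# pairwise latent distance matrices; posterior-predictive per-gene
# histogram divergences on a held-out split; embedding consistency across
# random gene subsets; and classifier-based cell-type separability.

#' Score recovery of latent pairwise distances
#'
#' Compares the Euclidean pairwise distance matrix of the true latent
#' positions with that of an estimated embedding using the Spearman
#' correlation of their upper-triangle entries. Because only relative
#' distances enter, the score is invariant to rotation, reflection,
#' translation and positive scaling of either embedding.
#'
#' @param Z_true,Z_hat N x K matrices of latent coordinates (the two may
#'   have different column counts); N >= 3.
#' @return object of class `"distance_score"`: `spearman`, `sse` (sum of
#'   squared differences after scaling each distance matrix to unit mean),
#'   and the distance matrices `F_true`, `F_hat`.
#' @export
distance_recovery_score <- function(Z_true, Z_hat) {
  Z_true <- as.matrix(Z_true); Z_hat <- as.matrix(Z_hat)
  if (nrow(Z_true) != nrow(Z_hat))
    stop("`Z_true` and `Z_hat` must have the same number of rows")
  if (nrow(Z_true) < 3)
    stop("need at least 3 points to correlate pairwise distances")
  dt <- dist(Z_true)
  dh <- dist(Z_hat)
  rho <- cor(as.numeric(dt), as.numeric(dh), method = "spearman")
  sse <- sum((as.numeric(dt) / mean(dt) - as.numeric(dh) / mean(dh))^2)
  structure(list(spearman = rho, sse = sse,
                 F_true = as.matrix(dt), F_hat = as.matrix(dh)),
            class = "distance_score")
}

#' @export
print.distance_score <- function(x, ...) {
  cat(sprintf("Distance recovery: Spearman = %.4f (n = %d points)\n",
              x$spearman, nrow(x$F_true)))
  invisible(x)
}

#' L1 divergence between two binned distributions
#'
#' Bins both samples into `n_bins` equal-width intervals spanning their
#' pooled range, normalizes the two histograms, and returns the sum of
#' absolute differences of bin proportions — a quantity in `[0, 2]`, with
#' 0 for identical histograms and 2 for disjoint supports. If all values in
#' both samples coincide the divergence is 0 by convention.
#'
#' @param observed,predicted nonempty numeric samples.
#' @param n_bins number of bins (default 30).
#' @param breaks optional explicit bin edges (overrides the pooled range;
#'   values outside are clamped to the end bins).
#' @return scalar divergence in `[0, 2]`.
#' @export
histogram_divergence <- function(observed, predicted, n_bins = 30,
                                 breaks = NULL) {
  if (length(observed) == 0 || length(predicted) == 0)
    stop("both samples must be nonempty")
  if (is.null(breaks)) {
    lo <- min(observed, predicted)
    hi <- max(observed, predicted)
    if (lo == hi) return(0)
    breaks <- seq(lo, hi, length.out = n_bins + 1)
  }
  bin <- function(x) {
    idx <- findInterval(x, breaks, rightmost.closed = TRUE, all.inside = TRUE)
    tabulate(idx, nbins = length(breaks) - 1) / length(x)
  }
  sum(abs(bin(observed) - bin(predicted)))
}

# Posterior-predictive draws per method on the training fit.
predictive_draws <- function(fit, n_draw, seed) {
  if (inherits(fit, "zifa")) simulate(fit, nsim = n_draw, seed = seed)$Y
  else simulate(fit, nsim = n_draw, seed = seed)
}

#' Posterior-predictive goodness-of-fit study
#'
#' Splits cells 70/30 into training and test sets, fits each requested
#' method on the training cells, draws posterior-predictive samples from
#' each fitted generative model (the zero-inflated fit includes the dropout
#' stage; FA/PPCA are purely Gaussian), and computes the per-gene histogram
#' divergence between the predictive draws and the held-out observed
#' values. Methods without a generative law (PCA) are rejected.
#'
#' @param y cells-by-genes matrix with at least 10 cells.
#' @param K latent dimensions used by every method (default 5).
#' @param methods subset of `c("zifa", "fa", "ppca")`.
#' @param train_fraction fraction of cells used for fitting (default 0.70).
#' @param n_bins histogram bins (default 30).
#' @param draw_multiple predictive sample size per gene as a multiple of
#'   the test-set size (default 10).
#' @param seed integer seed (split, fits, predictive draws).
#' @param ... passed on to [zifa()].
#' @return object of class `"predictive_check"`: `divergence` (genes x
#'   methods matrix of per-gene divergences), `win_fraction` (named vector:
#'   for each non-ZIFA method, the fraction of genes where ZIFA's
#'   divergence is strictly smaller), `n_train`, `n_test`.
#' @export
predictive_fit_study <- function(y, K = 5, methods = c("zifa", "fa", "ppca"),
                                 train_fraction = 0.7, n_bins = 30,
                                 draw_multiple = 10, seed = 1, ...) {
  check_matrix(y)
  methods <- match.arg(methods, c("zifa", "fa", "ppca"), several.ok = TRUE)
  if ("pca" %in% methods)
    stop("PCA has no posterior predictive distribution and cannot be scored")
  N <- nrow(y)
  if (N < 10) stop("need at least 10 cells for a 70/30 split")
  with_seed(seed, {
    idx <- sample.int(N)
    n_train <- floor(train_fraction * N)
    train <- y[idx[seq_len(n_train)], , drop = FALSE]
    test <- y[idx[(n_train + 1):N], , drop = FALSE]
    n_draw <- draw_multiple * nrow(test)
    draw_seeds <- sample.int(.Machine$integer.max, length(methods))
    fit_seed <- sample.int(.Machine$integer.max, 1)
    div <- sapply(seq_along(methods), function(mi) {
      m <- methods[mi]
      fit <- switch(m,
        zifa = zifa(train, K = K, seed = fit_seed, ...),
        fa = fit_fa(train, K),
        ppca = fit_ppca(train, K))
      pred <- predictive_draws(fit, n_draw, seed = draw_seeds[mi])
      vapply(seq_len(ncol(y)), function(j)
        histogram_divergence(test[, j], pred[, j], n_bins = n_bins),
        numeric(1))
    })
    colnames(div) <- methods
    win <- NULL
    if ("zifa" %in% methods) {
      others <- setdiff(methods, "zifa")
      win <- vapply(others, function(m) mean(div[, "zifa"] < div[, m]),
                    numeric(1))
    }
    structure(list(divergence = div, win_fraction = win,
                   n_train = n_train, n_test = nrow(test),
                   K = K, n_bins = n_bins),
              class = "predictive_check")
  })
}

#' @export
print.predictive_check <- function(x, ...) {
  cat(sprintf("Posterior-predictive check: %d genes, %d train / %d test cells, %d bins\n",
              nrow(x$divergence), x$n_train, x$n_test, x$n_bins))
  cat("  median divergence per method:\n")
  med <- apply(x$divergence, 2, median)
  for (m in names(med)) cat(sprintf("    %-5s %.3f\n", m, med[m]))
  if (!is.null(x$win_fraction))
    for (m in names(x$win_fraction))
      cat(sprintf("  ZIFA beats %s on %.1f%% of genes\n",
                  m, 100 * x$win_fraction[m]))
  invisible(x)
}

#' Consistency of embeddings across random gene subsets
#'
#' Repeatedly samples a random gene subset, fits each method, and records
#' the cell-to-cell distance matrix of the embedding; then computes the
#' Spearman correlation between every pair of repeats (so `n_repeats`
#' repeats yield `n_repeats * (n_repeats - 1) / 2` correlations per
#' method). Higher correlations mean the embedding depends less on which
#' genes — and hence which dropout events — were sampled.
#'
#' @param y cells-by-genes matrix with `D >= subset_size`.
#' @param n_repeats number of random subsets (default 100).
#' @param subset_size genes per subset (default 100).
#' @param methods subset of `c("zifa", "ppca", "fa", "pca")`.
#' @param K latent dimensions (default 5).
#' @param seed integer seed.
#' @param ... passed on to [zifa()].
#' @return list of class `"consistency_study"`: per-method numeric vectors
#'   of pairwise correlations, plus `n_failed` fit failures per method
#'   (failed repeats are skipped and counted).
#' @export
consistency_study <- function(y, n_repeats = 100, subset_size = 100,
                              methods = c("zifa", "ppca"), K = 5, seed = 1,
                              ...) {
  check_matrix(y)
  if (ncol(y) < subset_size)
    stop("`subset_size` exceeds the number of genes")
  methods <- match.arg(methods, c("zifa", "ppca", "fa", "pca"),
                       several.ok = TRUE)
  with_seed(seed, {
    subsets <- lapply(seq_len(n_repeats), function(r)
      sample.int(ncol(y), subset_size))
    fit_seeds <- sample.int(.Machine$integer.max, n_repeats)
    out <- list()
    for (m in methods) {
      dmats <- list()
      failed <- 0
      for (r in seq_len(n_repeats)) {
        ysub <- y[, subsets[[r]], drop = FALSE]
        keep <- colSums(ysub != 0) > 0
        emb <- tryCatch(switch(m,
            zifa = zifa(ysub[, keep, drop = FALSE], K = K,
                        seed = fit_seeds[r], ...)$Ez,
            ppca = fit_ppca(ysub, K)$Z_hat,
            fa = fit_fa(ysub, K)$Z_hat,
            pca = fit_pca(ysub, K)$Z_hat),
          error = function(e) NULL)
        if (is.null(emb)) failed <- failed + 1
        else dmats[[length(dmats) + 1]] <- as.numeric(dist(emb))
      }
      cors <- numeric(0)
      nr <- length(dmats)
      if (nr >= 2) {
        pairs <- utils::combn(nr, 2)
        cors <- vapply(seq_len(ncol(pairs)), function(p)
          cor(dmats[[pairs[1, p]]], dmats[[pairs[2, p]]],
              method = "spearman"), numeric(1))
      }
      out[[m]] <- list(correlations = cors, n_failed = failed)
    }
    structure(list(methods = out, n_repeats = n_repeats,
                   subset_size = subset_size, K = K),
              class = "consistency_study")
  })
}

#' @export
print.consistency_study <- function(x, ...) {
  cat(sprintf("Embedding consistency: %d repeats of %d genes\n",
              x$n_repeats, x$subset_size))
  for (m in names(x$methods)) {
    cs <- x$methods[[m]]
    cat(sprintf("  %-5s median pairwise Spearman = %.3f (%d correlations, %d failed fits)\n",
                m, median(cs$correlations), length(cs$correlations),
                cs$n_failed))
  }
  invisible(x)
}

#' Cell-type separability after dimensionality reduction
#'
#' For each of `n_subsets` random gene subsets, reduces the observed data
#' with PCA and with ZIFA to `K_out` dimensions, trains LDA/QDA classifiers
#' on the embedding against the true cluster labels, and records the
#' training misclassification rate — a proxy for how well cell types
#' separate in the latent space. When the simulation's dropout-free matrix
#' `X` is available, an exact-PCA baseline (PCA on `X`) is reported too.
#'
#' @param sim a `"zifa_sim"` carrying `cluster_labels` (see
#'   [simulate_cluster_scaffold()]).
#' @param K_out embedding dimension (default 10).
#' @param subset_size genes per subset (default 500; capped at D).
#' @param n_subsets number of subsets (default 30).
#' @param classifiers subset of `c("lda", "qda")`.
#' @param methods embedding methods, subset of `c("pca", "zifa")`.
#' @param seed integer seed.
#' @param ... passed on to [zifa()].
#' @return object of class `"separability_report"`: `rates`, a data frame
#'   with one row per subset x method x classifier (`error` = training
#'   misclassification rate; method `"exact_pca"` is the dropout-free
#'   baseline), and `dropout_rate` of the input matrix. Subsets where QDA
#'   fails (singular class covariance) are recorded with `NA`.
#' @export
separability_study <- function(sim, K_out = 10, subset_size = 500,
                               n_subsets = 30,
                               classifiers = c("lda", "qda"),
                               methods = c("pca", "zifa"), seed = 1, ...) {
  stopifnot(inherits(sim, "zifa_sim"))
  if (is.null(sim$cluster_labels))
    stop("`sim` carries no cluster labels; use simulate_cluster_scaffold()")
  classifiers <- match.arg(classifiers, c("lda", "qda"), several.ok = TRUE)
  methods <- match.arg(methods, c("pca", "zifa"), several.ok = TRUE)
  labels <- sim$cluster_labels
  D <- ncol(sim$Y)
  subset_size <- min(subset_size, D)
  train_error <- function(emb, classifier) {
    fit <- tryCatch(switch(classifier,
                           lda = MASS::lda(emb, grouping = labels),
                           qda = MASS::qda(emb, grouping = labels)),
                    error = function(e) NULL)
    if (is.null(fit)) return(NA_real_)
    mean(predict(fit, emb)$class != labels)
  }
  with_seed(seed, {
    fit_seeds <- sample.int(.Machine$integer.max, n_subsets)
    rows <- list()
    for (s in seq_len(n_subsets)) {
      genes <- sample.int(D, subset_size)
      ysub <- sim$Y[, genes, drop = FALSE]
      keep <- colSums(ysub != 0) > 0
      embeddings <- list()
      for (m in methods)
        embeddings[[m]] <- switch(m,
          pca = fit_pca(ysub, K_out)$Z_hat,
          zifa = zifa(ysub[, keep, drop = FALSE], K = K_out,
                      seed = fit_seeds[s], ...)$Ez)
      embeddings[["exact_pca"]] <-
        fit_pca(sim$X[, genes, drop = FALSE], K_out)$Z_hat
      for (m in names(embeddings))
        for (cl in classifiers)
          rows[[length(rows) + 1]] <- data.frame(
            subset = s, method = m, classifier = cl,
            error = train_error(embeddings[[m]], cl))
    }
    structure(list(rates = do.call(rbind, rows),
                   dropout_rate = mean(sim$Y == 0),
                   K_out = K_out, subset_size = subset_size,
                   n_subsets = n_subsets),
              class = "separability_report")
  })
}

#' @export
print.separability_report <- function(x, ...) {
  cat(sprintf("Cell-type separability: %d subsets of %d genes -> %d dims (input dropout %.2f)\n",
              x$n_subsets, x$subset_size, x$K_out, x$dropout_rate))
  agg <- stats::aggregate(error ~ method + classifier, data = x$rates,
                          FUN = mean, na.rm = TRUE)
  for (i in seq_len(nrow(agg)))
    cat(sprintf("  %-9s %-3s mean error %.3f\n",
                agg$method[i], agg$classifier[i], agg$error[i]))
  invisible(x)
}
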