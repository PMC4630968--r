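# zifar: zero-inflated factor analysis for single-cell expression data

Single-cell RNA-seq log-expression matrices contain an abundance of exact
zeros from *dropout events* — transcripts present in a cell that yield no
reads, through technical sampling at low transcript numbers or stochastic
transcription. Standard linear dimensionality reduction (PCA, probabilistic
PCA, factor analysis) assumes Gaussian measurements and is distorted by
this zero-inflation. `zifar` implements a factor-analysis model with an
explicit dropout layer, for analysts who want PCA-style low-dimensional
embeddings that remain reliable when a large fraction of the matrix is
zero.

## Model

For cells *i* = 1…*N* and genes *j* = 1…*D*, with latent dimension
*K* ≪ *D*:

    z_i  ~ Normal(0, I_K)                         latent position
    x_i | z_i ~ Normal(A z_i + mu, W)             latent expression,
                                                  W = diag(sigma_1^2 … sigma_D^2)
    h_ij | x_ij ~ Bernoulli(exp(-lambda x_ij^2))  dropout indicator
    y_ij = x_ij if h_ij = 0, else 0               observed log read count

The dropout probability decays as a double exponential in the latent
expression level, capturing the empirical relationship between a gene's
dropout rate and its mean nonzero expression; the decay parameter `lambda`
is shared across genes. Fitting is by EM with closed-form E-step moments:
conditioned on `z`, a zero entry's Gaussian factor tilted by
`exp(-lambda x^2)` collapses to a pseudo-observation of 0 with variance
inflated to `sigma_j^2 + 1/(2 lambda)`, so the joint posterior over the
latent position and the hidden expression at zeros stays Gaussian. An
exact variant and a block-approximate variant (disjoint random gene
blocks, cost linear in *D*) are provided, plus a tied-noise-variance
variant (a zero-inflated analogue of probabilistic PCA).

## Worked example

```r
library(zifar)

sim <- simulate_factor_data(N = 150, D = 50, K = 10, sigma2 = 0.3,
                            lam = 0.1, seed = 1)
mean(sim$Y == 0)                    # 0.428 — 43% of entries dropped out

fit <- zifa(sim$Y, K = 10, method = "exact", seed = 1)
fit
#> Zero-inflated factor analysis fit (exact EM)
#>   N = 150 cells, D = 50 genes, K = 10 latent dimensions
#>   lambda = 0.1008, dropout fraction = 0.428
#>   log-likelihood -9206.25 after 98 iterations (converged)

distance_recovery_score(sim$Z, fit$Ez)$spearman
#> [1] 0.7882295
distance_recovery_score(sim$Z, fit_pca(sim$Y, 10)$Z_hat)$spearman
#> [1] 0.6331748
```

The fitted `lambda` recovers the generating value 0.1, and the Spearman
agreement between true and estimated cell-to-cell latent distances (the
rotation-invariant currency for comparing embeddings) is distinctly higher
for the dropout-aware fit than for PCA on the same matrix. `predict()`
embeds new cells, `fitted()` returns dropout-imputed expression,
`simulate()` draws posterior-predictive cells, and `plot()` shows the
latent map.

For real data: `read_expression()` reads CSV/TSV/MatrixMarket in either
orientation, and `filter_genes()` applies a zero-fraction cutoff (genes
zero in more than ~95% of cells carry little signal and slow the EM; genes
that are all zero must be removed). A thin command-line front end is
installed at `exec/zifa` with `fit`, `simulate` and `evaluate`
subcommands.

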