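# Shared fixtures: small, fast configurations built in code.

suppressPackageStartupMessages(library(SummarizedExperiment))

# A small cohort for unit tests (full-size generation is exercised in the
# acceptance tests).
smallConfig <- function(seed = 101L, ...) {
  syntheticConfig(nLean = 15L, nOverweight = 15L, nObese = 15L,
                  nPaired = 10L, seed = seed, ...)
}

# Zero-structure config: no correlations, no group shifts.
independentConfig <- function(n, seed = 202L, nPaired = 10L) {
  cfg <- syntheticConfig(seed = seed)
  vars <- c(cfg@batGenes, cfg@inflammatoryGenes, cfg@covariateNames)
  R <- diag(length(vars)); dimnames(R) <- list(vars, vars)
  shifts <- cfg@groupShifts; shifts[] <- 0
  syntheticConfig(nLean = n, nOverweight = 0L, nObese = 0L,
                  nPaired = nPaired, targetCorrelation = R,
                  groupShifts = shifts, seed = seed)
}

# Fast ANN configuration for unit tests.
fastAnnConfig <- function(seed = 303L, mcResamples = 8L, ...) {
  annConfig(mcResamples = mcResamples, seed = seed, ...)
}

# A panel with a planted linear structural network: each child is a
# linear combination of its parents plus independent noise (latent
# scale), exponentiated to expression.
plantedPanel <- function(nGenes, edges, weights, n, seed,
                         noiseSd = 0.5) {
  genes <- sprintf("G%02d", seq_len(nGenes))
  A <- matrix(0, nGenes, nGenes, dimnames = list(genes, genes))
  for (k in seq_len(nrow(edges))) A[edges[k, 1], edges[k, 2]] <- weights[k]
  set.seed(seed)
  eps <- matrix(rnorm(n * nGenes), n, nGenes)
  X <- t(solve(diag(nGenes) - t(A), t(eps)))
  E <- exp(noiseSd * X)
  colnames(E) <- genes
  rownames(E) <- sprintf("S%03d", seq_len(n))
  list(expression = E, adjacency = A, genes = genes)
}
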