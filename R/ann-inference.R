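# The ANNi core: per-target single-hidden-layer neural models under Monte
# Carlo cross-validation; signed interactions read off the trained
# prediction weights.

#' Build an ANN inference configuration
#'
#' Defaults follow the minimal-MLP convention of ANN-inference pipelines:
#' one hidden layer of 3 sigmoidal units with a linear output, 50 Monte
#' Carlo 60/20/20 train/validation/test resamples, full-batch gradient
#' descent with momentum, early stopping on the validation error, and
#' min-max scaling fitted on the training fraction only (no leakage).
#'
#' @param hiddenUnits hidden units (default 3).
#' @param mcResamples Monte Carlo resamples (default 50).
#' @param splitFractions train/validation/test fractions (default
#'   0.6/0.2/0.2).
#' @param maxEpochs maximum training epochs (default 1000).
#' @param learningRate gradient-descent step (default 0.2).
#' @param momentum momentum coefficient (default 0.9).
#' @param earlyStopPatience epochs without validation improvement before
#'   stopping (default 30).
#' @param scaling \code{"unit_interval"} (default) or \code{"zscore"}.
#' @param seed integer seed for splits and weight initialisation.
#' @return a validated [AnnConfig-class].
#' @export
annConfig <- function(hiddenUnits = 3L, mcResamples = 50L,
                      splitFractions = c(0.6, 0.2, 0.2),
                      maxEpochs = 1000L, learningRate = 0.2,
                      momentum = 0.9, earlyStopPatience = 30L,
                      scaling = "unit_interval", seed = 20230419L) {
  methods::new("AnnConfig",
    hiddenUnits = as.integer(hiddenUnits),
    mcResamples = as.integer(mcResamples),
    splitFractions = as.numeric(splitFractions),
    maxEpochs = as.integer(maxEpochs),
    learningRate = as.numeric(learningRate),
    momentum = as.numeric(momentum),
    earlyStopPatience = as.integer(earlyStopPatience),
    scaling = scaling, seed = as.integer(seed))
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# Full-batch gradient descent with momentum on half-MSE; early stopping on
# the validation error, returning the weights at the best validation
# epoch.
trainMlp <- function(Xtr, ytr, Xval, yval, config) {
  p <- ncol(Xtr); h <- config@hiddenUnits; n <- nrow(Xtr)
  lr <- config@learningRate; mom <- config@momentum
  W1 <- matrix(runif(p * h, -0.5, 0.5), p, h)
  b1 <- runif(h, -0.5, 0.5)
  w2 <- runif(h, -0.5, 0.5)
  b2 <- runif(1, -0.5, 0.5)
  vW1 <- matrix(0, p, h); vb1 <- numeric(h); vw2 <- numeric(h); vb2 <- 0
  best <- list(W1 = W1, b1 = b1, w2 = w2, b2 = b2, valMse = Inf,
               epoch = 0L)
  wait <- 0L
  for (e in seq_len(config@maxEpochs)) {
    A <- sigmoid(sweep(Xtr %*% W1, 2, b1, "+"))
    r <- drop(A %*% w2) + b2 - ytr
    gw2 <- drop(crossprod(A, r)) / n
    gb2 <- mean(r)
    D <- (r %o% w2) * A * (1 - A)
    gW1 <- crossprod(Xtr, D) / n
    gb1 <- colMeans(D)
    vW1 <- mom * vW1 - lr * gW1; vb1 <- mom * vb1 - lr * gb1
    vw2 <- mom * vw2 - lr * gw2; vb2 <- mom * vb2 - lr * gb2
    W1 <- W1 + vW1; b1 <- b1 + vb1; w2 <- w2 + vw2; b2 <- b2 + vb2
    Av <- sigmoid(sweep(Xval %*% W1, 2, b1, "+"))
    valMse <- mean((drop(Av %*% w2) + b2 - yval)^2)
    if (valMse < best$valMse - 1e-9) {
      best <- list(W1 = W1, b1 = b1, w2 = w2, b2 = b2, valMse = valMse,
                   epoch = e)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= config@earlyStopPatience) break
    }
  }
  best
}

mlpPredict <- function(fit, X) {
  drop(sigmoid(sweep(X %*% fit$W1, 2, fit$b1, "+")) %*% fit$w2) + fit$b2
}

# Scaling fitted on the training fraction only.
fitScaler <- function(Xtr, scaling) {
  if (scaling == "unit_interval") {
    lo <- apply(Xtr, 2, min); hi <- apply(Xtr, 2, max)
    list(a = lo, b = pmax(hi - lo, 1e-12))
  } else {
    mu <- colMeans(Xtr); sd <- apply(Xtr, 2, sd)
    list(a = mu, b = pmax(sd, 1e-12))
  }
}

applyScaler <- function(X, sc) {
  sweep(sweep(X, 2, sc$a, "-"), 2, sc$b, "/")
}

#' Fit Monte Carlo cross-validated neural models for one target gene
#'
#' For each resample, samples are split at random into
#' train/validation/test fractions; a single-hidden-layer feed-forward
#' model predicting the target gene from all other genes is trained by
#' gradient descent with early stopping on the validation fraction;
#' first-layer and second-layer weights and the test-fraction performance
#' are recorded. Fully reproducible from the configuration seed.
#'
#' @param expression samples x genes matrix (or cohort
#'   SummarizedExperiment); >= 10 samples and >= 2 predictor genes.
#' @param targetGene column to predict.
#' @param config an [AnnConfig-class].
#' @return list with \code{target}, \code{predictors}, \code{dropped}
#'   (zero-variance predictors removed with a warning), and \code{fits},
#'   one record per resample: \code{W1} (predictors x hidden), \code{b1},
#'   \code{w2} (hidden), \code{b2}, \code{valMse}, \code{testMse},
#'   \code{testR2}, \code{composite} (per-predictor summed weight
#'   products).
#' @export
fitTargetModels <- function(expression, targetGene, config = annConfig()) {
  methods::validObject(config)
  E <- asSampleMatrix(expression)
  if (!targetGene %in% colnames(E))
    stop("target gene '", targetGene, "' not present")
  if (nrow(E) < 10L) stop("need at least 10 samples")
  predictors <- setdiff(colnames(E), targetGene)
  vars <- apply(E[, predictors, drop = FALSE], 2, var)
  dropped <- predictors[vars == 0]
  if (length(dropped)) {
    warning("dropping zero-variance predictor(s): ",
            paste(dropped, collapse = ", "))
    predictors <- setdiff(predictors, dropped)
  }
  if (length(predictors) < 2L)
    stop("need at least 2 non-degenerate predictor genes")
  n <- nrow(E)
  f <- config@splitFractions
  nTr <- max(2L, round(f[1] * n))
  nVal <- max(1L, round(f[2] * n))
  if (nTr + nVal >= n) stop("too few samples for the configured split")
  X <- E[, predictors, drop = FALSE]
  y <- E[, targetGene]
  seeds <- deriveSeeds(config@seed + match(targetGene, colnames(E)),
                       config@mcResamples)
  fits <- lapply(seq_len(config@mcResamples), function(rIdx) {
    withSeed(seeds[rIdx], {
      idx <- sample(n)
      tr <- idx[seq_len(nTr)]
      va <- idx[nTr + seq_len(nVal)]
      te <- idx[(nTr + nVal + 1L):n]
      scX <- fitScaler(X[tr, , drop = FALSE], config@scaling)
      scY <- fitScaler(matrix(y[tr], ncol = 1), config@scaling)
      Xs <- applyScaler(X, scX)
      ys <- (y - scY$a) / scY$b
      fit <- trainMlp(Xs[tr, , drop = FALSE], ys[tr],
                      Xs[va, , drop = FALSE], ys[va], config)
      pred <- mlpPredict(fit, Xs[te, , drop = FALSE])
      testMse <- mean((pred - ys[te])^2)
      denom <- sum((ys[te] - mean(ys[te]))^2)
      testR2 <- if (denom > 0) 1 - sum((pred - ys[te])^2) / denom
                else NA_real_
      list(W1 = fit$W1, b1 = fit$b1, w2 = fit$w2, b2 = fit$b2,
           valMse = fit$valMse, testMse = testMse, testR2 = testR2,
           composite = setNames(drop(fit$W1 %*% fit$w2), predictors))
    })
  })
  list(target = targetGene, predictors = predictors, dropped = dropped,
       fits = fits)
}

#' Infer the signed gene-interaction matrix (ANNi)
#'
#' Trains one Monte Carlo cross-validated model per target gene and reads
#' the composite influence of every predictor on every target off the
#' trained weights: per resample, the influence of gene i on target j is
#' the sum over hidden units of the first-layer weight (i to hidden) times
#' the second-layer weight (hidden to output); entries are averaged across
#' resamples with sign retained, and their across-resample standard
#' deviation is kept as a dispersion matrix. The diagonal is structurally
#' zero.
#'
#' @param expression samples x genes matrix or cohort
#'   SummarizedExperiment; >= 3 genes.
#' @param config an [AnnConfig-class].
#' @param includeCovariates optional clinical covariate names (e.g.
#'   \code{c("bmi", "endotoxin")}) appended as pseudo-genes when
#'   \code{expression} is a SummarizedExperiment; they are modelled
#'   identically to genes.
#' @return an [InteractionMatrix-class].
#' @seealso [collapseInfluence()], [rankInteractions()],
#'   [exportNetwork()]
#' @export
interactionMatrix <- function(expression, config = annConfig(),
                              includeCovariates = NULL) {
  E <- asSampleMatrix(expression)
  if (!is.null(includeCovariates)) {
    if (!methods::is(expression, "SummarizedExperiment"))
      stop("includeCovariates requires a SummarizedExperiment input")
    cd <- SummarizedExperiment::colData(expression)
    miss <- setdiff(includeCovariates, colnames(cd))
    if (length(miss))
      stop("unknown covariate(s): ", paste(miss, collapse = ", "))
    extra <- as.matrix(as.data.frame(cd[, includeCovariates,
                                        drop = FALSE]))
    E <- cbind(E, extra)
  }
  genes <- colnames(E)
  p <- length(genes)
  if (p < 3L) stop("interaction inference needs at least 3 genes")
  W <- matrix(0, p, p, dimnames = list(genes, genes))
  disp <- matrix(0, p, p, dimnames = list(genes, genes))
  medR2 <- setNames(numeric(p), genes)
  for (j in genes) {
    fm <- fitTargetModels(E, j, config)
    comp <- vapply(fm$fits, `[[`, numeric(length(fm$predictors)),
                   "composite")
    if (is.null(dim(comp)))
      comp <- matrix(comp, nrow = length(fm$predictors))
    W[fm$predictors, j] <- rowMeans(comp)
    disp[fm$predictors, j] <- apply(comp, 1, sd)
    medR2[j] <- median(vapply(fm$fits, `[[`, 1, "testR2"))
  }
  diag(W) <- 0
  diag(disp) <- 0
  methods::new("InteractionMatrix", genes = genes, W = W,
               dispersion = disp, nResamples = config@mcResamples,
               medianTestR2 = medR2)
}

#' Collapse an interaction matrix into per-gene influence summaries
#'
#' The matrix is collapsed by taking the sum of values from and to each
#' gene: row sums give the influence a gene exerts on the rest of the
#' panel, column sums the influence it receives. Ranks are assigned on
#' the signed values ascending (rank 1 = most negative = most
#' suppressive), with ties broken by gene-name lexical order.
#'
#' @param im an [InteractionMatrix-class] (or a plain signed square
#'   matrix with dimnames).
#' @return data.frame with columns \code{gene}, \code{influence_exerted},
#'   \code{influence_received}, \code{rank_exerted},
#'   \code{rank_received}. The grand totals of the two influence columns
#'   are equal (both are the grand sum of W).
#' @export
collapseInfluence <- function(im) {
  W <- if (methods::is(im, "InteractionMatrix")) im@W else im
  genes <- rownames(W) %||% sprintf("g%d", seq_len(nrow(W)))
  exerted <- rowSums(W)
  received <- colSums(W)
  rankSigned <- function(v) {
    ord <- order(v, genes)
    r <- integer(length(v)); r[ord] <- seq_along(v); r
  }
  data.frame(gene = genes,
             influence_exerted = unname(exerted),
             influence_received = unname(received),
             rank_exerted = rankSigned(exerted),
             rank_received = rankSigned(received),
             stringsAsFactors = FALSE)
}

#' Rank interactions by absolute influence weight
#'
#' All off-diagonal entries sorted by |W| descending, each carrying sign,
#' magnitude and across-resample dispersion; ties are broken by (source,
#' target) lexical order for determinism.
#'
#' @param im an [InteractionMatrix-class].
#' @param topK number of edges to return; at most
#'   \code{|genes| * (|genes| - 1)}. Default: all.
#' @return data.frame with columns \code{source}, \code{target},
#'   \code{weight}, \code{sign}, \code{dispersion}, \code{rank}.
#' @export
rankInteractions <- function(im, topK = NULL) {
  p <- length(im@genes)
  maxK <- p * (p - 1L)
  if (is.null(topK)) topK <- maxK
  if (topK <= 0) stop("topK must be positive")
  if (topK > maxK) stop("topK exceeds the number of ordered gene pairs")
  idx <- which(row(im@W) != col(im@W))
  src <- im@genes[row(im@W)[idx]]
  tgt <- im@genes[col(im@W)[idx]]
  w <- im@W[idx]
  d <- im@dispersion[idx]
  ord <- order(-abs(w), src, tgt)
  out <- data.frame(source = src[ord], target = tgt[ord],
                    weight = w[ord], sign = sign(w[ord]),
                    dispersion = d[ord], rank = seq_along(ord),
                    stringsAsFactors = FALSE)
  head(out, topK)
}

#' Recovery of a planted network by the inferred interaction matrix
#'
#' Scores edge recovery two ways: the AUROC of |W| as a score against the
#' planted directed adjacency, and the number of planted interactions
#' found among the top \code{top} distinct gene pairs of the ranked edge
#' list. The composite-weight score is near-symmetric (both orientations
#' of a dependence score high), so top-k recovery is assessed at the
#' unordered-pair level.
#'
#' @param im an [InteractionMatrix-class].
#' @param adjacency planted signed adjacency (same gene order).
#' @param top number of top distinct pairs to inspect (default 5).
#' @return list with \code{auroc}, \code{topPairsRecovered},
#'   \code{nPlanted}.
#' @export
edgeRecovery <- function(im, adjacency, top = 5L) {
  W <- im@W
  off <- row(W) != col(W)
  score <- abs(W)[off]
  truth <- (adjacency != 0)[off]
  rk <- rank(score)
  nPos <- sum(truth); nNeg <- sum(!truth)
  auroc <- (sum(rk[truth]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
  edges <- rankInteractions(im)
  pairKey <- function(a, b)
    paste(pmin(a, b), pmax(a, b), sep = "|")
  topPairs <- unique(pairKey(edges$source, edges$target))[seq_len(top)]
  g <- im@genes
  plantedIdx <- which(adjacency != 0, arr.ind = TRUE)
  plantedPairs <- unique(pairKey(g[plantedIdx[, 1]], g[plantedIdx[, 2]]))
  list(auroc = auroc,
       topPairsRecovered = sum(topPairs %in% plantedPairs),
       nPlanted = length(plantedPairs))
}

#' Permutation null for interaction weights
#'
#' Destroys all between-gene association by independently permuting each
#' gene's sample vector (marginals preserved), re-runs the full inference
#' with the same configuration, and returns the requested quantile of the
#' null |W| distribution. Real entries exceeding the 95th null percentile
#' beyond the nominal rate indicate miscalibration.
#'
#' @param expression samples x genes matrix or SummarizedExperiment.
#' @param config an [AnnConfig-class].
#' @param nPermutations number of permuted datasets (default 1; each costs
#'   a full inference run).
#' @param probs quantile(s) of the pooled null |W| values (default 0.95).
#' @param seed seed for the permutations (default derived from config).
#' @return named numeric quantile(s) of the null |W| distribution.
#' @export
interactionNullQuantile <- function(expression, config = annConfig(),
                                    nPermutations = 1L, probs = 0.95,
                                    seed = NULL) {
  E <- asSampleMatrix(expression)
  if (is.null(seed)) seed <- config@seed + 7919L
  permSeeds <- deriveSeeds(seed, nPermutations)
  nullW <- unlist(lapply(seq_len(nPermutations), function(k) {
    Ep <- withSeed(permSeeds[k],
      apply(E, 2, function(col) col[sample(length(col))]))
    rownames(Ep) <- rownames(E)
    cfg <- config
    cfg@seed <- config@seed + k
    im <- interactionMatrix(Ep, cfg)
    abs(im@W[row(im@W) != col(im@W)])
  }))
  quantile(nullW, probs = probs, names = TRUE)
}
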