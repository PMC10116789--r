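test_that("ANN configuration enforces its invariants", {
  expect_error(annConfig(splitFractions = c(0.5, 0.2, 0.2)), "sum")
  expect_error(annConfig(hiddenUnits = 0L), "hiddenUnits")
  expect_error(annConfig(mcResamples = 1L), "mcResamples")
  expect_error(annConfig(scaling = "rank"), "scaling")
})

test_that("model fitting is reproducible from the seed", {
  panel <- plantedPanel(4, cbind(1, 2), 1.0, n = 60, seed = 51)
  cfg <- fastAnnConfig(seed = 52, mcResamples = 4L)
  f1 <- fitTargetModels(panel$expression, "G02", cfg)
  f2 <- fitTargetModels(panel$expression, "G02", cfg)
  expect_identical(f1, f2)
  f3 <- fitTargetModels(panel$expression, "G02",
                        fastAnnConfig(seed = 53, mcResamples = 4L))
  expect_false(identical(f1$fits[[1]]$W1, f3$fits[[1]]$W1))
})

test_that("a noiseless linear target is learned almost perfectly", {
  set.seed(54)
  n <- 200
  X <- matrix(rnorm(n * 3), n, 3,
              dimnames = list(NULL, c("a", "b", "c")))
  E <- cbind(X, target = 2 * X[, "a"] - 1.5 * X[, "b"])
  fm <- fitTargetModels(E, "target", fastAnnConfig(seed = 55,
                                                   mcResamples = 10L))
  r2 <- vapply(fm$fits, `[[`, 1, "testR2")
  expect_gte(median(r2), 0.99)
})

test_that("a pure-noise target is not learnable", {
  set.seed(56)
  n <- 200
  E <- matrix(rnorm(n * 4), n, 4,
              dimnames = list(NULL, c("a", "b", "c", "noise")))
  fm <- fitTargetModels(E, "noise", fastAnnConfig(seed = 57,
                                                  mcResamples = 10L))
  r2 <- vapply(fm$fits, `[[`, 1, "testR2")
  expect_lte(median(r2), 0.1)
})

test_that("degenerate predictors are dropped with a warning", {
  set.seed(58)
  E <- cbind(matrix(rnorm(120), 40, 3), flat = rep(2, 40))
  colnames(E) <- c("a", "b", "t", "flat")
  expect_warning(
    fm <- fitTargetModels(E, "t", fastAnnConfig(mcResamples = 3L)),
    "flat")
  expect_false("flat" %in% fm$predictors)
  expect_error(fitTargetModels(E[1:8, ], "t"), "10 samples")
  expect_error(fitTargetModels(E, "zzz"), "not present")
})

test_that("interaction signs track planted monotone dependencies", {
  hits <- 0L
  for (k in 1:10) {
    set.seed(60 + k)
    n <- 120
    x <- rnorm(n)
    E <- cbind(x = x, y = 2 * x + rnorm(n, 0, 0.3), z = rnorm(n))
    im <- interactionMatrix(E, fastAnnConfig(seed = 70 + k,
                                             mcResamples = 6L))
    if (im@W["x", "y"] > 0) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})

test_that("the interaction matrix has a structurally zero diagonal", {
  panel <- plantedPanel(5, cbind(1, 2), 0.9, n = 80, seed = 61)
  im <- interactionMatrix(panel$expression,
                          fastAnnConfig(seed = 62, mcResamples = 4L))
  expect_true(all(diag(im@W) == 0))
  expect_true(all(diag(im@dispersion) == 0))
  expect_true(all(im@dispersion >= 0))
  expect_identical(im@genes, panel$genes)
})

test_that("influence collapse equals the row/column-sum definition", {
  W <- matrix(c(0, 2, -1,
                1, 0, 3,
                -2, 1, 0), 3, 3, byrow = TRUE,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  ci <- collapseInfluence(W)
  expect_equal(ci$influence_exerted, c(1, 4, -1))
  expect_equal(ci$influence_received, c(-1, 3, 2))
  # conservation: both totals equal the grand sum
  expect_identical(sum(ci$influence_exerted), sum(W))
  expect_identical(sum(ci$influence_received), sum(W))
  # most negative = rank 1 (most suppressive)
  expect_equal(ci$rank_exerted[ci$gene == "c"], 1L)

  # all-zero matrix: ranks fall back to lexical order
  W0 <- matrix(0, 3, 3, dimnames = dimnames(W))
  ci0 <- collapseInfluence(W0)
  expect_equal(ci0$rank_exerted, 1:3)
  expect_equal(ci0$influence_exerted, rep(0, 3))

  # random matrix against an independent oracle
  set.seed(63)
  Wr <- matrix(rnorm(100), 10, 10,
               dimnames = list(letters[1:10], letters[1:10]))
  diag(Wr) <- 0
  cir <- collapseInfluence(Wr)
  expect_equal(cir$influence_exerted, unname(apply(Wr, 1, sum)),
               tolerance = 1e-15)
  expect_equal(cir$influence_received, unname(apply(Wr, 2, sum)),
               tolerance = 1e-15)
})

test_that("edge ranking orders by |W| with deterministic tie-breaks", {
  W <- matrix(0, 3, 3, dimnames = list(c("a", "b", "c"),
                                       c("a", "b", "c")))
  W["a", "b"] <- 5; W["b", "c"] <- -5; W["c", "a"] <- 0.1
  im <- methods::new("InteractionMatrix", genes = c("a", "b", "c"),
                     W = W, dispersion = abs(W) * 0,
                     nResamples = 2L,
                     medianTestR2 = c(a = 0, b = 0, c = 0))
  edges <- rankInteractions(im)
  expect_equal(nrow(edges), 6L)
  # |5| ties broken lexically by (source, target)
  expect_equal(edges$source[1:2], c("a", "b"))
  expect_equal(edges$weight[1:2], c(5, -5))
  top1 <- rankInteractions(im, topK = 1L)
  expect_equal(nrow(top1), 1L)
  expect_error(rankInteractions(im, 0), "positive")
  expect_error(rankInteractions(im, 7L), "exceeds")
})

test_that("network export round-trips through SIF and GraphML", {
  edges <- data.frame(source = c("UCP1", "IL6", "CD14"),
                      target = c("CIDEA", "UCP1", "SLC27A2"),
                      weight = c(1.23456789012345, -0.5, 2e-7),
                      sign = c(1, -1, 1),
                      dispersion = c(0.1, 0.2, 0.3))
  sif <- tempfile(fileext = ".sif")
  exportNetwork(edges, sif, "sif")
  lines <- readLines(sif)
  expect_length(lines, 3L)
  expect_match(lines[1], "^UCP1\tinfluences_pos\tCIDEA$")
  expect_match(lines[2], "^IL6\tinfluences_neg\tUCP1$")
  sidecar <- sub("\\.sif$", "_edges.csv", sif)
  expect_true(file.exists(sidecar))
  expect_equal(read.csv(sidecar)$weight, edges$weight, tolerance = 1e-12)

  gml <- tempfile(fileext = ".graphml")
  exportNetwork(edges, gml, "graphml")
  back <- readNetworkGraphML(gml)
  expect_equal(back$weight, edges$weight, tolerance = 1e-12)
  expect_equal(back$dispersion, edges$dispersion, tolerance = 1e-12)
  expect_equal(back$sign[2], -1)
  expect_error(exportNetwork(edges, tempfile(), "dot"), "unknown format")
  expect_error(exportNetwork(edges[0, ], tempfile(), "sif"), "empty")
})

test_that("interaction inference is deterministic end to end", {
  panel <- plantedPanel(4, cbind(1, 2), 1.0, n = 60, seed = 64)
  cfg <- fastAnnConfig(seed = 65, mcResamples = 3L)
  im1 <- interactionMatrix(panel$expression, cfg)
  im2 <- interactionMatrix(panel$expression, cfg)
  expect_identical(im1@W, im2@W)
  expect_identical(im1@dispersion, im2@dispersion)
})

test_that("covariates can be appended as pseudo-genes", {
  cfg <- smallConfig(seed = 66)
  se <- generateCohort(cfg)[1:4, ]
  im <- interactionMatrix(se, fastAnnConfig(seed = 67, mcResamples = 3L),
                          includeCovariates = c("bmi", "endotoxin"))
  expect_true(all(c("bmi", "endotoxin") %in% im@genes))
  expect_equal(length(im@genes), 6L)
  expect_error(
    interactionMatrix(se, fastAnnConfig(mcResamples = 3L),
                      includeCovariates = "nope"), "unknown covariate")
})
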