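#' Build a synthetic cohort configuration with study defaults
#'
#' The defaults emulate the cross-sectional adipose-tissue cohort the
#' analysis workflow was designed for: three BMI strata (lean n = 44,
#' overweight n = 49, obese n = 63), a paired pre/post-bariatric-surgery
#' subcohort (n = 26), a brown-adipose (BAT) gene panel (UCP1, PGC1A,
#' CIDEA, ELOVL3, PLIN5, SLC27A2) anti-correlated with an inflammatory
#' panel (IL6, MCP1, TNFA, IL1B, CD14, CD68, IL10), with BMI and with
#' circulating endotoxin, plus clinical covariates whose group means follow
#' the cohort characteristics table (glucose, insulin, lipids, weight).
#'
#' Correlation targets are stated on the latent scale: transcript values
#' are generated as exponentiated Gaussians (lognormal, strictly positive,
#' right-skewed as qPCR fold-changes are), so for genes the target is the
#' correlation of log-expression.
#'
#' @param nLean,nOverweight,nObese,nPaired stratum sample sizes.
#' @param batGenes,inflammatoryGenes gene panels.
#' @param covariateNames clinical covariates; defaults cover BMI (kg/m^2),
#'   endotoxin (EU/mL), glucose (mmol/L), insulin (pmol/L), weight and
#'   ideal weight (kg), total cholesterol, HDL and triglycerides (mmol/L).
#' @param targetCorrelation symmetric unit-diagonal matrix over
#'   \code{c(genes, covariates)}; \code{NULL} builds the default block
#'   structure (BAT vs inflammation -0.30, BAT vs BMI -0.40, BAT vs
#'   endotoxin -0.35, inflammation vs BMI +0.35, inflammation vs endotoxin
#'   +0.40, within-panel +0.35, and metabolic covariate couplings).
#'   Repaired to positive semidefiniteness via [repairCorrelation()];
#'   irreparable matrices are rejected.
#' @param groupShifts matrix (rows \code{lean}, \code{overweight},
#'   \code{obese}, \code{pre}; columns variables) of latent-scale mean
#'   offsets. Defaults: BAT genes fall and inflammatory genes rise with
#'   adiposity.
#' @param plantedNetwork signed gene x gene adjacency (zero diagonal)
#'   superimposed on the latent gene block as a linear structural model;
#'   default all-zero (correlation targets alone shape the data).
#' @param noiseSd latent SD of log-expression (default 0.5).
#' @param covariateMeans,covariateSds natural-scale covariate means/SDs per
#'   group; \code{NULL} uses the cohort characteristics defaults.
#' @param surgeryEffect named post-minus-pre mean shifts on the measurement
#'   scale; \code{NULL} uses defaults (endotoxin falls, BAT expression
#'   rises, weight/glucose/insulin fall).
#' @param deltaSd named per-variable SDs of the post-minus-pre change.
#' @param seed integer seed (default 20230419).
#' @return a validated [SyntheticConfig-class].
#' @examples
#' cfg <- syntheticConfig(seed = 1)
#' cfg
#' @export
syntheticConfig <- function(
    nLean = 44L, nOverweight = 49L, nObese = 63L, nPaired = 26L,
    batGenes = c("UCP1", "PGC1A", "CIDEA", "ELOVL3", "PLIN5", "SLC27A2"),
    inflammatoryGenes = c("IL6", "MCP1", "TNFA", "IL1B", "CD14", "CD68",
                          "IL10"),
    covariateNames = c("bmi", "endotoxin", "glucose", "insulin", "weight",
                       "ideal_weight", "total_cholesterol", "hdl", "tg"),
    targetCorrelation = NULL,
    groupShifts = NULL,
    plantedNetwork = NULL,
    noiseSd = 0.5,
    covariateMeans = NULL,
    covariateSds = NULL,
    surgeryEffect = NULL,
    deltaSd = NULL,
    seed = 20230419L) {
  genes <- c(batGenes, inflammatoryGenes)
  vars <- c(genes, covariateNames)
  groups <- c("lean", "overweight", "obese", "pre")

  if (is.null(targetCorrelation))
    targetCorrelation <- defaultCorrelationTargets(batGenes,
                                                   inflammatoryGenes,
                                                   covariateNames)
  targetCorrelation <- repairCorrelation(targetCorrelation)

  if (is.null(groupShifts)) {
    groupShifts <- matrix(0, 4, length(vars),
                          dimnames = list(groups, vars))
    # BAT expression falls, inflammatory expression rises with adiposity
    # (latent log scale, in units of noiseSd = fold-changes of ~1.4-2.2x).
    groupShifts[, batGenes] <-
      matrix(c(0, -0.35, -0.7, -0.8), 4, length(batGenes))
    groupShifts[, inflammatoryGenes] <-
      matrix(c(0, 0.35, 0.7, 0.8), 4, length(inflammatoryGenes))
  }
  if (is.null(plantedNetwork))
    plantedNetwork <- matrix(0, length(genes), length(genes),
                             dimnames = list(genes, genes))

  if (is.null(covariateMeans)) {
    covariateMeans <- defaultCovariateMeans()[covariateNames, , drop = FALSE]
  }
  if (is.null(covariateSds)) {
    covariateSds <- defaultCovariateSds()[covariateNames, , drop = FALSE]
  }

  if (is.null(surgeryEffect)) {
    surgeryEffect <- setNames(numeric(length(vars)), vars)
    surgeryEffect[batGenes] <- 0.4            # expression units (rises)
    surgeryEffect[inflammatoryGenes] <- -0.2  # falls
    se <- c(bmi = -5.51, endotoxin = -2.5, glucose = -2.26,
            insulin = -14.74, weight = -15.9, ideal_weight = 0,
            total_cholesterol = -0.65, hdl = -0.04, tg = -0.44)
    keep <- intersect(names(se), covariateNames)
    surgeryEffect[keep] <- se[keep]
  }
  if (is.null(deltaSd)) {
    deltaSd <- setNames(rep(0.3, length(vars)), vars)
    ds <- c(bmi = 2.0, endotoxin = 1.2, glucose = 1.2, insulin = 9,
            weight = 5.5, ideal_weight = 0, total_cholesterol = 0.5,
            hdl = 0.12, tg = 0.45)
    keep <- intersect(names(ds), covariateNames)
    deltaSd[keep] <- ds[keep]
  }

  methods::new("SyntheticConfig",
    nLean = as.integer(nLean), nOverweight = as.integer(nOverweight),
    nObese = as.integer(nObese), nPaired = as.integer(nPaired),
    batGenes = batGenes, inflammatoryGenes = inflammatoryGenes,
    covariateNames = covariateNames,
    targetCorrelation = targetCorrelation,
    groupShifts = groupShifts, plantedNetwork = plantedNetwork,
    noiseSd = noiseSd,
    covariateMeans = covariateMeans, covariateSds = covariateSds,
    surgeryEffect = surgeryEffect, deltaSd = deltaSd,
    seed = as.integer(seed))
}

#' Default latent correlation targets for the browning/inflammation panels
#'
#' @inheritParams syntheticConfig
#' @return symmetric unit-diagonal matrix over
#'   \code{c(batGenes, inflammatoryGenes, covariateNames)} (possibly not
#'   exactly positive semidefinite; callers repair it).
#' @export
defaultCorrelationTargets <- function(batGenes, inflammatoryGenes,
                                      covariateNames) {
  vars <- c(batGenes, inflammatoryGenes, covariateNames)
  R <- diag(length(vars))
  dimnames(R) <- list(vars, vars)
  setBlock <- function(R, a, b, r) {
    a <- intersect(a, vars); b <- intersect(b, vars)
    for (i in a) for (j in b) if (i != j) { R[i, j] <- r; R[j, i] <- r }
    R
  }
  R <- setBlock(R, batGenes, batGenes, 0.35)
  R <- setBlock(R, inflammatoryGenes, inflammatoryGenes, 0.35)
  R <- setBlock(R, batGenes, inflammatoryGenes, -0.30)
  R <- setBlock(R, batGenes, "bmi", -0.40)
  R <- setBlock(R, batGenes, "endotoxin", -0.35)
  R <- setBlock(R, batGenes, "weight", -0.35)
  R <- setBlock(R, inflammatoryGenes, "bmi", 0.35)
  R <- setBlock(R, inflammatoryGenes, "endotoxin", 0.40)
  R <- setBlock(R, inflammatoryGenes, "weight", 0.30)
  R <- setBlock(R, "bmi", "endotoxin", 0.40)
  R <- setBlock(R, "bmi", "insulin", 0.40)
  R <- setBlock(R, "bmi", "glucose", 0.30)
  R <- setBlock(R, "bmi", "hdl", -0.30)
  R <- setBlock(R, "bmi", "weight", 0.85)
  R <- setBlock(R, "weight", "insulin", 0.35)
  R <- setBlock(R, "weight", "glucose", 0.25)
  R <- setBlock(R, "weight", "endotoxin", 0.35)
  R <- setBlock(R, "glucose", "insulin", 0.50)
  R
}

# Natural-scale covariate means per group (columns lean/overweight/obese/
# pre-surgery), following the cohort characteristics table; total
# cholesterol derived as LDL + HDL + TG/2.2; endotoxin EU/mL chosen as a
# realistic gradient rising with BMI and highest pre-surgery.
defaultCovariateMeans <- function() {
  m <- rbind(
    bmi               = c(22.14, 27.30, 36.35, 42.21),
    endotoxin         = c(4.0, 5.5, 7.0, 8.5),
    glucose           = c(3.58, 3.63, 5.92, 9.22),
    insulin           = c(39.79, 64.58, 62.97, 31.90),
    weight            = c(64.0, 78.9, 105.1, 122.0),
    ideal_weight      = c(72.25, 72.25, 72.25, 72.25),
    total_cholesterol = c(7.71, 7.47, 6.37, 4.99),
    hdl               = c(1.74, 1.53, 1.35, 1.08),
    tg                = c(3.11, 3.26, 2.65, 1.83)
  )
  colnames(m) <- c("lean", "overweight", "obese", "pre")
  m
}

defaultCovariateSds <- function() {
  s <- c(bmi = 3.5, endotoxin = 1.8, glucose = 1.2, insulin = 30,
         weight = 12, ideal_weight = 3, total_cholesterol = 1.2,
         hdl = 0.4, tg = 1.0)
  m <- matrix(rep(s, 4), ncol = 4,
              dimnames = list(names(s),
                              c("lean", "overweight", "obese", "pre")))
  m
}

# Latent draw for n samples: MVN over all variables, planted network
# applied to the gene block as a linear structural model
# x_genes = (I - A^T)^{-1} eps_genes.
latentDraw <- function(n, config) {
  R <- config@targetCorrelation
  Z <- rmvnormLatent(n, R)
  genes <- c(config@batGenes, config@inflammatoryGenes)
  A <- config@plantedNetwork
  if (any(A != 0)) {
    M <- diag(length(genes)) - t(A)
    if (abs(det(M)) < 1e-10)
      stop("plantedNetwork feedback is too strong: I - t(A) is singular")
    Z[, genes] <- t(solve(M, t(Z[, genes, drop = FALSE])))
  }
  Z
}

# Map a latent draw plus group labels to natural-scale tables.
materialise <- function(Z, groupLabels, config) {
  genes <- c(config@batGenes, config@inflammatoryGenes)
  covs <- config@covariateNames
  shifts <- config@groupShifts[groupLabels, , drop = FALSE]
  expr <- exp(shifts[, genes, drop = FALSE] +
                config@noiseSd * Z[, genes, drop = FALSE])
  mu <- t(config@covariateMeans[, groupLabels, drop = FALSE])
  sdv <- t(config@covariateSds[, groupLabels, drop = FALSE])
  clin <- pmax(mu + sdv * (Z[, covs, drop = FALSE] +
                             shifts[, covs, drop = FALSE]), 0)
  list(expr = expr, clin = clin)
}

makeTruth <- function(config) {
  methods::new("PlantedTruth",
    adjacency = config@plantedNetwork,
    correlationTargets = config@targetCorrelation,
    groupEffects = config@groupShifts,
    surgeryEffects = config@surgeryEffect,
    seed = config@seed)
}

#' Generate a synthetic cross-sectional cohort
#'
#' Draws \code{nLean + nOverweight + nObese} samples from a latent
#' multivariate Gaussian with the configured correlation targets, applies
#' group mean shifts, exponentiates the gene block into strictly positive
#' relative-expression values, and maps covariates onto their natural
#' clinical scales (concentrations floored at zero). Identical
#' configuration and seed give bit-identical output.
#'
#' @param config a [SyntheticConfig-class].
#' @param depot optional depot label recycled across samples (e.g.
#'   \code{"Sc"} or \code{"Om"}); stored in the sample metadata.
#' @return a [SummarizedExperiment::SummarizedExperiment] with assay
#'   \code{relexpr} (genes x samples), clinical covariates plus
#'   \code{group} in \code{colData}, and the [PlantedTruth-class] in
#'   \code{metadata(x)$truth}.
#' @examples
#' se <- generateCohort(syntheticConfig(seed = 7))
#' dim(se)
#' table(SummarizedExperiment::colData(se)$group)
#' @export
generateCohort <- function(config, depot = "Sc") {
  methods::validObject(config)
  n <- config@nLean + config@nOverweight + config@nObese
  if (n < 1L) stop("cohort is empty: all group sizes are zero")
  groupLabels <- rep(c("lean", "overweight", "obese"),
                     times = c(config@nLean, config@nOverweight,
                               config@nObese))
  out <- withSeed(config@seed, {
    Z <- latentDraw(n, config)
    materialise(Z, groupLabels, config)
  })
  sampleIds <- sprintf("S%04d", seq_len(n))
  assay <- t(out$expr)
  colnames(assay) <- sampleIds
  cd <- S4Vectors::DataFrame(
    sample_id = sampleIds,
    group = groupLabels,
    depot = rep_len(depot, n),
    out$clin,
    row.names = sampleIds)
  SummarizedExperiment::SummarizedExperiment(
    assays = list(relexpr = assay),
    colData = cd,
    metadata = list(truth = makeTruth(config), config = config))
}

#' Generate a synthetic paired pre/post-surgery subcohort
#'
#' Each of \code{nPaired} subjects receives a pre-surgery draw from the
#' latent model (group \code{"pre"}) and a post-surgery value
#' \code{post = pre + delta}, where the per-subject change vector is
#' multivariate normal with mean \code{surgeryEffect} and correlation
#' given by the configured targets (so planted delta-couplings, e.g.
#' between the change in endotoxin and the change in a BAT gene, are the
#' Pearson correlations the delta analysis measures). Post-surgery
#' expression is floored at 1% of the pre value to preserve positivity;
#' covariate concentrations are floored at zero.
#'
#' @param config a [SyntheticConfig-class] with \code{nPaired >= 3}.
#' @return a [SummarizedExperiment::SummarizedExperiment] with
#'   \code{2 * nPaired} columns, \code{colData} columns \code{subject} and
#'   \code{timepoint} (\code{"pre"}/\code{"post"}) plus covariates, and the
#'   [PlantedTruth-class] in \code{metadata(x)$truth}.
#' @examples
#' pe <- generatePaired(syntheticConfig(seed = 7))
#' table(SummarizedExperiment::colData(pe)$timepoint)
#' @export
generatePaired <- function(config) {
  methods::validObject(config)
  n <- config@nPaired
  if (n < 3L) stop("paired design needs nPaired >= 3")
  genes <- c(config@batGenes, config@inflammatoryGenes)
  vars <- c(genes, config@covariateNames)
  out <- withSeed(config@seed + 1L, {
    Z <- latentDraw(n, config)
    pre <- materialise(Z, rep("pre", n), config)
    delta <- rmvnormLatent(n, config@targetCorrelation,
                           mu = config@surgeryEffect[vars],
                           sd = config@deltaSd[vars])
    list(pre = pre, delta = delta)
  })
  preExpr <- out$pre$expr
  postExpr <- pmax(preExpr + out$delta[, genes, drop = FALSE],
                   0.01 * preExpr)
  preClin <- out$pre$clin
  postClin <- pmax(preClin + out$delta[, config@covariateNames,
                                       drop = FALSE], 0)
  subj <- sprintf("P%03d", seq_len(n))
  ids <- c(paste0(subj, "_pre"), paste0(subj, "_post"))
  assay <- t(rbind(preExpr, postExpr))
  dimnames(assay) <- list(genes, ids)
  cd <- S4Vectors::DataFrame(
    sample_id = ids,
    subject = rep(subj, 2),
    timepoint = rep(c("pre", "post"), each = n),
    rbind(preClin, postClin),
    row.names = ids)
  SummarizedExperiment::SummarizedExperiment(
    assays = list(relexpr = assay),
    colData = cd,
    metadata = list(truth = makeTruth(config), config = config))
}

#' Simulate duplicate qPCR Ct plates from an expression table
#'
#' For every sample and gene, emits two replicate cycle-threshold values
#' such that the collapsed difference to the housekeeping gene satisfies
#' \code{Ct_gene - Ct_hk = -log2(relative expression)} plus replicate
#' noise; housekeeping rows are included per sample. With zero replicate
#' noise, quantification inverts the simulation exactly.
#'
#' @param expression a cohort
#'   [SummarizedExperiment::SummarizedExperiment] or a samples x genes
#'   matrix of strictly positive relative expression.
#' @param noiseSd replicate Ct noise SD in cycles (default 0.15).
#' @param housekeeping housekeeping gene name (default \code{"L19"}).
#' @param baselineCt mean housekeeping Ct in cycles (default 18).
#' @param replicates replicates per sample x gene (default 2, as assays
#'   run in duplicate).
#' @param seed integer seed.
#' @return long-format data.frame with columns \code{sample_id},
#'   \code{gene}, \code{replicate}, \code{ct}.
#' @examples
#' se <- generateCohort(syntheticConfig(nLean = 4L, nOverweight = 0L,
#'                                      nObese = 0L, seed = 1))
#' ct <- generateCtPlates(se, noiseSd = 0, seed = 1)
#' head(ct)
#' @export
generateCtPlates <- function(expression, noiseSd = 0.15,
                             housekeeping = "L19", baselineCt = 18,
                             replicates = 2L, seed = 20230419L) {
  E <- asSampleMatrix(expression)
  if (any(E <= 0))
    stop("expression values must be strictly positive to simulate Ct")
  if (noiseSd < 0) stop("noiseSd must be >= 0")
  samples <- rownames(E) %||% sprintf("S%04d", seq_len(nrow(E)))
  genes <- colnames(E)
  if (housekeeping %in% genes)
    stop("housekeeping gene must not be part of the expression panel")
  # target Ct per sample x gene: hk baseline - log2(expression)
  ctGene <- sweep(-log2(E), 1, baselineCt, "+")
  allGenes <- c(genes, housekeeping)
  grid <- expand.grid(replicate = seq_len(replicates),
                      gene = allGenes, sample_id = samples,
                      stringsAsFactors = FALSE)
  base <- ifelse(grid$gene == housekeeping, baselineCt,
                 ctGene[cbind(match(grid$sample_id, samples),
                              match(grid$gene, genes))])
  ct <- withSeed(seed, base + rnorm(nrow(grid), 0, noiseSd))
  data.frame(sample_id = grid$sample_id, gene = grid$gene,
             replicate = grid$replicate, ct = ct,
             stringsAsFactors = FALSE)
}

#' Accessors for generated cohorts
#'
#' Convenience extractors for the containers produced by the generator:
#' the samples x genes expression matrix, the clinical table, and the
#' planted ground truth.
#'
#' @param se a [SummarizedExperiment::SummarizedExperiment] from
#'   [generateCohort()] or [generatePaired()].
#' @return \code{expressionTable}: samples x genes numeric matrix;
#'   \code{clinicalTable}: data.frame of sample metadata;
#'   \code{plantedTruth}: the [PlantedTruth-class] or \code{NULL}.
#' @export
expressionTable <- function(se) {
  t(SummarizedExperiment::assay(se, "relexpr"))
}

#' @rdname expressionTable
#' @export
clinicalTable <- function(se) {
  as.data.frame(SummarizedExperiment::colData(se))
}

#' @rdname expressionTable
#' @export
plantedTruth <- function(se) {
  S4Vectors::metadata(se)$truth
}
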