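#' @import methods
#' @importFrom stats aov coef complete.cases cor cor.test kruskal.test lm
#'   median p.adjust pchisq pnorm pt pf qnorm quantile rnorm runif sd
#'   setNames t.test var wilcox.test TukeyHSD model.tables na.omit
#' @importFrom utils head read.csv write.csv
NULL

#' Configuration of the synthetic cohort generator
#'
#' Describes the study design emulated by [generateCohort()] and
#' [generatePaired()]: three BMI strata (lean, overweight, obese), a paired
#' pre/post-bariatric-surgery subcohort, a brown-adipose (BAT) gene panel and
#' an inflammatory gene panel, clinical covariates on their natural scales,
#' a target correlation matrix on the latent scale, per-group mean shifts,
#' an optional planted signed interaction network over the genes, and
#' post-minus-pre surgery effects for the paired design.
#'
#' @slot nLean,nOverweight,nObese numbers of samples per BMI stratum.
#' @slot nPaired number of subjects measured pre and post surgery.
#' @slot batGenes,inflammatoryGenes character vectors of gene names.
#' @slot covariateNames clinical covariate names (BMI, endotoxin, ...).
#' @slot targetCorrelation symmetric unit-diagonal correlation matrix over
#'   all variables (genes then covariates) on the latent scale. Transcript
#'   values are exponentiated, so for genes this is the correlation of
#'   log-expression.
#' @slot groupShifts matrix (groups x variables) of latent-scale mean
#'   offsets; rows \code{lean}, \code{overweight}, \code{obese}, \code{pre}.
#' @slot plantedNetwork signed gene x gene adjacency (zero diagonal); entry
#'   \code{[i, j]} is the direct linear influence of gene i on gene j on the
#'   latent scale.
#' @slot noiseSd latent standard deviation of log-expression (> 0).
#' @slot covariateMeans,covariateSds natural-scale means/SDs per covariate
#'   (rows) and group (columns).
#' @slot surgeryEffect named post-minus-pre mean shifts on the measurement
#'   scale (expression units for genes, natural units for covariates).
#' @slot deltaSd named per-variable SD of the post-minus-pre change.
#' @slot seed integer seed recorded into [PlantedTruth-class].
#'
#' @seealso [syntheticConfig()] for the constructor with study defaults.
#' @export
setClass("SyntheticConfig",
  slots = c(
    nLean = "integer", nOverweight = "integer", nObese = "integer",
    nPaired = "integer",
    batGenes = "character", inflammatoryGenes = "character",
    covariateNames = "character",
    targetCorrelation = "matrix",
    groupShifts = "matrix",
    plantedNetwork = "matrix",
    noiseSd = "numeric",
    covariateMeans = "matrix", covariateSds = "matrix",
    surgeryEffect = "numeric", deltaSd = "numeric",
    seed = "integer"
  )
)

setValidity("SyntheticConfig", function(object) {
  msg <- character()
  vars <- c(object@batGenes, object@inflammatoryGenes, object@covariateNames)
  if (anyDuplicated(vars))
    msg <- c(msg, "gene and covariate names must be unique")
  ns <- c(object@nLean, object@nOverweight, object@nObese, object@nPaired)
  if (any(ns < 0L)) msg <- c(msg, "all sample sizes must be >= 0")
  if (length(object@noiseSd) != 1L || object@noiseSd <= 0)
    msg <- c(msg, "noiseSd must be a single positive number")
  R <- object@targetCorrelation
  if (!identical(dim(R), c(length(vars), length(vars))))
    msg <- c(msg, "targetCorrelation dimensions must match genes + covariates")
  else {
    if (max(abs(R - t(R))) > 1e-8)
      msg <- c(msg, "targetCorrelation must be symmetric")
    if (max(abs(diag(R) - 1)) > 1e-8)
      msg <- c(msg, "targetCorrelation must have unit diagonal")
    if (any(abs(R) > 1 + 1e-8))
      msg <- c(msg, "targetCorrelation entries must lie in [-1, 1]")
  }
  A <- object@plantedNetwork
  ng <- length(c(object@batGenes, object@inflammatoryGenes))
  if (!identical(dim(A), c(ng, ng)))
    msg <- c(msg, "plantedNetwork must be gene x gene")
  else if (any(diag(A) != 0))
    msg <- c(msg, "plantedNetwork must have a zero diagonal")
  if (length(msg)) msg else TRUE
})

#' Ground truth planted by the synthetic generator
#'
#' Returned alongside generated data so that downstream recovery tests can
#' compare inferred networks, correlations, and effects against what was
#' actually planted.
#'
#' @slot adjacency signed gene x gene planted network (zero diagonal).
#' @slot correlationTargets the latent correlation matrix actually used
#'   (after positive-semidefinite repair, if any was needed).
#' @slot groupEffects latent-scale group mean shifts (groups x variables).
#' @slot surgeryEffects named post-minus-pre mean shifts.
#' @slot seed the seed the data were generated from.
#' @export
setClass("PlantedTruth",
  slots = c(
    adjacency = "matrix",
    correlationTargets = "matrix",
    groupEffects = "matrix",
    surgeryEffects = "numeric",
    seed = "integer"
  )
)

setValidity("PlantedTruth", function(object) {
  A <- object@adjacency
  if (nrow(A) != ncol(A)) return("adjacency must be square")
  if (any(diag(A) != 0)) return("adjacency must have a zero diagonal")
  TRUE
})

#' Configuration of the ANN inference engine
#'
#' Hyper-parameters of the per-target neural models and of the Monte Carlo
#' cross-validation loop. See [annConfig()] for defaults and rationale.
#'
#' @slot hiddenUnits number of sigmoidal hidden units (>= 1).
#' @slot mcResamples number of Monte Carlo train/validation/test resamples
#'   (>= 2).
#' @slot splitFractions train/validation/test fractions summing to 1.
#' @slot maxEpochs maximum gradient-descent epochs per fit.
#' @slot learningRate gradient-descent step size (> 0).
#' @slot momentum classical momentum coefficient in [0, 1).
#' @slot earlyStopPatience epochs without validation improvement before
#'   stopping.
#' @slot scaling \code{"unit_interval"} (min-max on the training fraction)
#'   or \code{"zscore"} (training-fraction mean/SD).
#' @slot seed integer seed governing splits and weight initialisation.
#' @export
setClass("AnnConfig",
  slots = c(
    hiddenUnits = "integer", mcResamples = "integer",
    splitFractions = "numeric", maxEpochs = "integer",
    learningRate = "numeric", momentum = "numeric",
    earlyStopPatience = "integer", scaling = "character",
    seed = "integer"
  )
)

setValidity("AnnConfig", function(object) {
  msg <- character()
  if (object@hiddenUnits < 1L) msg <- c(msg, "hiddenUnits must be >= 1")
  if (object@mcResamples < 2L) msg <- c(msg, "mcResamples must be >= 2")
  f <- object@splitFractions
  if (length(f) != 3L || any(f <= 0) || abs(sum(f) - 1) > 1e-9)
    msg <- c(msg, "splitFractions must be 3 positive numbers summing to 1")
  if (object@learningRate <= 0) msg <- c(msg, "learningRate must be > 0")
  if (object@momentum < 0 || object@momentum >= 1)
    msg <- c(msg, "momentum must lie in [0, 1)")
  if (!object@scaling %in% c("unit_interval", "zscore"))
    msg <- c(msg, "scaling must be 'unit_interval' or 'zscore'")
  if (length(msg)) msg else TRUE
})

#' Signed gene-interaction matrix inferred by ANNi
#'
#' Entry \code{W[i, j]} is the composite input-to-output prediction weight
#' of gene i in the neural model predicting gene j (sum over hidden units of
#' first-layer x second-layer weight products), averaged across Monte Carlo
#' resamples with sign retained. The diagonal is structurally zero.
#'
#' @slot genes ordered variable names (genes, plus any covariates appended
#'   as pseudo-genes).
#' @slot W signed influence matrix, rows = source, columns = target.
#' @slot dispersion across-resample standard deviation of each entry.
#' @slot nResamples number of Monte Carlo resamples averaged.
#' @slot medianTestR2 per-target median test-fraction R-squared, a
#'   validation-error filter on model quality.
#' @seealso [interactionMatrix()], [collapseInfluence()],
#'   [rankInteractions()]
#' @export
setClass("InteractionMatrix",
  slots = c(
    genes = "character",
    W = "matrix",
    dispersion = "matrix",
    nResamples = "integer",
    medianTestR2 = "numeric"
  )
)

setValidity("InteractionMatrix", function(object) {
  p <- length(object@genes)
  msg <- character()
  if (!identical(dim(object@W), c(p, p)))
    msg <- c(msg, "W must be |genes| x |genes|")
  else if (any(diag(object@W) != 0))
    msg <- c(msg, "W must have a zero diagonal")
  if (!identical(dim(object@dispersion), c(p, p)))
    msg <- c(msg, "dispersion must be |genes| x |genes|")
  else if (any(object@dispersion < 0))
    msg <- c(msg, "dispersion must be >= 0 elementwise")
  if (length(msg)) msg else TRUE
})

#' Outcome of a routed hypothesis test
#'
#' Records which branch (parametric or non-parametric) the normality
#' assessment selected, the omnibus statistic and p-value, per-group sample
#' sizes, and post-hoc pairwise comparisons when an omnibus test over three
#' or more groups was run.
#'
#' @slot testName the test actually performed.
#' @slot statistic named test statistic(s); two-way designs carry one entry
#'   per effect.
#' @slot pValue named p-value(s), each in [0, 1].
#' @slot nPerGroup named per-group sample sizes.
#' @slot branch \code{"parametric"} or \code{"nonparametric"}.
#' @slot posthoc data.frame of pairwise comparisons (empty when no post hoc
#'   applies).
#' @slot notes diagnostic messages (degenerate inputs, routing warnings).
#' @export
setClass("StatResult",
  slots = c(
    testName = "character",
    statistic = "numeric",
    pValue = "numeric",
    nPerGroup = "integer",
    branch = "character",
    posthoc = "data.frame",
    notes = "character"
  )
)

setValidity("StatResult", function(object) {
  p <- object@pValue
  if (any(!is.na(p) & (p < 0 | p > 1))) return("p-values must lie in [0, 1]")
  if (!object@branch %in% c("parametric", "nonparametric"))
    return("branch must be 'parametric' or 'nonparametric'")
  TRUE
})

#' Outcome of a Pearson correlation analysis
#'
#' @slot variableX,variableY variable names.
#' @slot r Pearson correlation coefficient in [-1, 1].
#' @slot pValue two-tailed p-value from the t transform
#'   \eqn{t = r \sqrt{(n-2)/(1-r^2)}}.
#' @slot n number of pairwise-complete observations used.
#' @slot nExcluded observations dropped as incomplete.
#' @slot logX,logY whether the variable was natural-log-transformed before
#'   the correlation (log routing of non-normal positive variables).
#' @export
setClass("CorrelationResult",
  slots = c(
    variableX = "character", variableY = "character",
    r = "numeric", pValue = "numeric",
    n = "integer", nExcluded = "integer",
    logX = "logical", logY = "logical"
  )
)

setValidity("CorrelationResult", function(object) {
  if (!is.na(object@r) && abs(object@r) > 1 + 1e-12)
    return("|r| must be <= 1")
  if (!is.na(object@pValue) && (object@pValue < 0 || object@pValue > 1))
    return("pValue must lie in [0, 1]")
  if (object@n < 3L) return("n must be >= 3")
  TRUE
})

#' Panel-by-panel matrix of Pearson correlations
#'
#' Result of [correlationMatrix()]: parallel matrices of r, p, effective n,
#' significance stars (* < 0.05, ** < 0.01, *** < 0.001, **** < 0.0001) and
#' log-routing flags, rows = first panel, columns = second panel.
#'
#' @slot r,p,n,stars,logged parallel matrices.
#' @export
setClass("CorrelationMatrix",
  slots = c(
    r = "matrix", p = "matrix", n = "matrix",
    stars = "matrix", logged = "matrix"
  )
)
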