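#' Extract p-value(s) from a result object
#' @param object a [StatResult-class] or [CorrelationResult-class].
#' @return named numeric vector of p-values (length 1 except for factorial
#'   designs).
#' @export
setGeneric("pValue", function(object) standardGeneric("pValue"))

#' Which branch the normality routing selected
#' @param object a [StatResult-class].
#' @return \code{"parametric"} or \code{"nonparametric"}.
#' @export
setGeneric("branch", function(object) standardGeneric("branch"))

#' Post-hoc pairwise comparison table
#' @param object a [StatResult-class].
#' @return data.frame of pairwise contrasts (empty when no omnibus post hoc
#'   was run).
#' @export
setGeneric("posthoc", function(object) standardGeneric("posthoc"))

#' Signed influence weights of an interaction matrix
#' @param object an [InteractionMatrix-class].
#' @return numeric matrix, rows = source gene, columns = target gene.
#' @export
setGeneric("interactionWeights",
  function(object) standardGeneric("interactionWeights"))

#' Across-resample dispersion of interaction weights
#' @param object an [InteractionMatrix-class].
#' @return numeric matrix of standard deviations across Monte Carlo
#'   resamples.
#' @export
setGeneric("interactionDispersion",
  function(object) standardGeneric("interactionDispersion"))

#' @export
#' @describeIn pValue p-values of a routed hypothesis test
setMethod("pValue", "StatResult", function(object) object@pValue)

#' @export
#' @describeIn pValue p-value of a Pearson correlation
setMethod("pValue", "CorrelationResult", function(object) object@pValue)

#' @export
#' @describeIn branch branch of a routed hypothesis test
setMethod("branch", "StatResult", function(object) object@branch)

#' @export
#' @describeIn posthoc post-hoc table of a routed hypothesis test
setMethod("posthoc", "StatResult", function(object) object@posthoc)

#' @export
#' @describeIn interactionWeights weights of an inferred network
setMethod("interactionWeights", "InteractionMatrix",
  function(object) object@W)

#' @export
#' @describeIn interactionDispersion dispersion of an inferred network
setMethod("interactionDispersion", "InteractionMatrix",
  function(object) object@dispersion)

setMethod("show", "StatResult", function(object) {
  cat("StatResult:", object@testName, "(", object@branch, "branch )\n")
  st <- object@statistic
  pv <- object@pValue
  for (i in seq_along(pv)) {
    cat(sprintf("  %s: statistic = %.4g, p = %.4g\n",
                names(pv)[i] %||% "omnibus", st[i], pv[i]))
  }
  cat("  n per group:",
      paste(sprintf("%s=%d", names(object@nPerGroup), object@nPerGroup),
            collapse = ", "), "\n")
  if (nrow(object@posthoc))
    cat("  post hoc:", nrow(object@posthoc), "pairwise comparisons\n")
  if (length(object@notes))
    cat("  notes:", paste(object@notes, collapse = "; "), "\n")
})

setMethod("show", "CorrelationResult", function(object) {
  tag <- function(l) if (l) " (log)" else ""
  cat(sprintf("CorrelationResult: %s%s vs %s%s\n",
              object@variableX, tag(object@logX),
              object@variableY, tag(object@logY)))
  cat(sprintf("  r = %.4f, p = %.4g, n = %d", object@r, object@pValue,
              object@n))
  if (object@nExcluded > 0L)
    cat(sprintf(" (%d incomplete pairs excluded)", object@nExcluded))
  cat("\n")
})

setMethod("show", "InteractionMatrix", function(object) {
  p <- length(object@genes)
  cat(sprintf(
    "InteractionMatrix: %d variables, %d Monte Carlo resamples\n",
    p, object@nResamples))
  aw <- abs(object@W)
  top <- order(aw, decreasing = TRUE)[seq_len(min(5L, p * (p - 1L)))]
  ij <- arrayInd(top, dim(aw))
  cat("  strongest interactions:\n")
  for (k in seq_len(nrow(ij))) {
    i <- ij[k, 1]; j <- ij[k, 2]
    cat(sprintf("    %s -> %s  W = %+.4f (sd %.4f)\n",
                object@genes[i], object@genes[j],
                object@W[i, j], object@dispersion[i, j]))
  }
})

setMethod("show", "SyntheticConfig", function(object) {
  cat("SyntheticConfig:\n")
  cat(sprintf("  cohort: lean n=%d, overweight n=%d, obese n=%d; paired n=%d\n",
              object@nLean, object@nOverweight, object@nObese,
              object@nPaired))
  cat("  BAT panel:", paste(object@batGenes, collapse = ", "), "\n")
  cat("  inflammatory panel:",
      paste(object@inflammatoryGenes, collapse = ", "), "\n")
  cat("  covariates:", paste(object@covariateNames, collapse = ", "), "\n")
  cat(sprintf("  latent noise sd: %.3g; planted edges: %d; seed: %d\n",
              object@noiseSd, sum(object@plantedNetwork != 0),
              object@seed))
})

setMethod("show", "PlantedTruth", function(object) {
  cat(sprintf("PlantedTruth: %d variables, %d planted edges, seed %d\n",
              nrow(object@correlationTargets), sum(object@adjacency != 0),
              object@seed))
})

setMethod("show", "AnnConfig", function(object) {
  cat(sprintf(
    paste0("AnnConfig: %d hidden units, %d MC resamples, split %s,\n",
           "  lr %.3g, momentum %.2f, max %d epochs, patience %d, ",
           "scaling '%s', seed %d\n"),
    object@hiddenUnits, object@mcResamples,
    paste(object@splitFractions, collapse = "/"),
    object@learningRate, object@momentum, object@maxEpochs,
    object@earlyStopPatience, object@scaling, object@seed))
})

setMethod("show", "CorrelationMatrix", function(object) {
  cat(sprintf("CorrelationMatrix: %d x %d cells\n",
              nrow(object@r), ncol(object@r)))
  print(round(object@r, 3))
})

#' @export
as.data.frame.CorrelationMatrix <- function(x, ...) {
  idx <- expand.grid(row = rownames(x@r), col = colnames(x@r),
                     stringsAsFactors = FALSE)
  data.frame(
    variable_x = idx$row, variable_y = idx$col,
    r = as.vector(x@r), p = as.vector(x@p), n = as.vector(x@n),
    stars = as.vector(x@stars), logged = as.vector(x@logged),
    stringsAsFactors = FALSE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
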