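#' Pearson correlation with per-variable log-transform routing
#'
#' Each variable is routed independently through [assessNormality()];
#' non-normal variables are natural-log-transformed before computing the
#' Pearson correlation, provided they are strictly positive (a variable
#' flagged for log with non-positive values is rejected by name). The
#' two-tailed p-value comes from the t transform
#' \eqn{t = r \sqrt{(n-2)/(1-r^2)}}.
#'
#' @param x,y equal-length numeric vectors; pairwise-complete n >= 3.
#' @param nameX,nameY variable names recorded in the result.
#' @param logRouting set \code{FALSE} to disable the log branch entirely
#'   (used for delta variables, which may be negative).
#' @return a [CorrelationResult-class].
#' @examples
#' set.seed(1); x <- rnorm(30)
#' pearsonWithLogRouting(x, 2 * x + rnorm(30, 0, 0.1))
#' @export
pearsonWithLogRouting <- function(x, y, nameX = "x", nameY = "y",
                                  logRouting = TRUE) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  keep <- is.finite(x) & is.finite(y)
  nExcluded <- sum(!keep)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) stop("need at least 3 pairwise-complete observations")
  if (var(x) == 0) stop("zero variance in ", nameX)
  if (var(y) == 0) stop("zero variance in ", nameY)
  routeVar <- function(v, nm) {
    if (!logRouting) return(list(v = v, logged = FALSE))
    rt <- withCallingHandlers(
      assessNormality(v),
      warning = function(w) invokeRestart("muffleWarning"))
    if (rt$branch == "nonparametric") {
      if (any(v <= 0))
        stop("variable '", nm, "' is routed for log transform but has ",
             "non-positive values")
      list(v = log(v), logged = TRUE)
    } else list(v = v, logged = FALSE)
  }
  rx <- routeVar(x, nameX)
  ry <- routeVar(y, nameY)
  ct <- cor.test(rx$v, ry$v, method = "pearson",
                 alternative = "two.sided")
  methods::new("CorrelationResult",
    variableX = nameX, variableY = nameY,
    r = unname(ct$estimate), pValue = ct$p.value,
    n = as.integer(n), nExcluded = as.integer(nExcluded),
    logX = rx$logged, logY = ry$logged)
}

# Resolve a variable (gene row or clinical column) from a paired cohort
# SummarizedExperiment into a per-sample vector.
pairedVariable <- function(se, name) {
  if (name %in% rownames(se))
    return(as.numeric(SummarizedExperiment::assay(se, "relexpr")[name, ]))
  cd <- SummarizedExperiment::colData(se)
  if (name %in% colnames(cd)) return(as.numeric(cd[[name]]))
  stop("unknown variable '", name, "': not a gene or clinical column")
}

#' Correlation of post-minus-pre changes in a paired design
#'
#' For each subject present at both timepoints, the change is measured by
#' subtracting the pre value from the post value for both variables; the
#' Pearson correlation of the two delta vectors follows, with log routing
#' disabled (changes may be negative). Subjects missing a timepoint are
#' excluded and counted in \code{nExcluded}.
#'
#' @param paired a paired [SummarizedExperiment::SummarizedExperiment]
#'   from [generatePaired()] (or equivalent with \code{subject} and
#'   \code{timepoint} columns, timepoints \code{"pre"}/\code{"post"}).
#' @param varX,varY variable names: gene names or clinical covariate
#'   columns (e.g. \code{"endotoxin"}).
#' @return a [CorrelationResult-class] on the delta scale.
#' @export
deltaCorrelation <- function(paired, varX, varY) {
  cd <- SummarizedExperiment::colData(paired)
  if (!all(c("subject", "timepoint") %in% colnames(cd)))
    stop("paired data needs 'subject' and 'timepoint' columns")
  tp <- as.character(cd$timepoint)
  subj <- as.character(cd$subject)
  complete <- intersect(subj[tp == "pre"], subj[tp == "post"])
  nExcl <- length(unique(subj)) - length(complete)
  if (length(complete) < 3L)
    stop("fewer than 3 subjects with both timepoints")
  vx <- pairedVariable(paired, varX)
  vy <- pairedVariable(paired, varY)
  idx <- function(s, t) which(subj == s & tp == t)[1]
  pre <- vapply(complete, function(s) idx(s, "pre"), 1L)
  post <- vapply(complete, function(s) idx(s, "post"), 1L)
  dx <- vx[post] - vx[pre]
  dy <- vy[post] - vy[pre]
  if (var(dx) == 0 || var(dy) == 0)
    stop("zero-variance deltas: no change to correlate")
  res <- pearsonWithLogRouting(dx, dy,
                               nameX = paste0("delta_", varX),
                               nameY = paste0("delta_", varY),
                               logRouting = FALSE)
  res@nExcluded <- as.integer(res@nExcluded + nExcl)
  res
}

#' Panel-by-panel Pearson correlation matrix
#'
#' Computes every pairwise correlation between two gene panels (e.g.
#' inflammatory markers against BAT-related genes) with per-variable log
#' routing, and attaches the star convention (* < 0.05, ** < 0.01,
#' *** < 0.001, **** < 0.0001).
#'
#' @param expression cohort SummarizedExperiment or samples x genes
#'   matrix.
#' @param panelX,panelY gene name vectors; unknown names are rejected and
#'   listed.
#' @param logRouting passed to [pearsonWithLogRouting()].
#' @return a [CorrelationMatrix-class] (rows = \code{panelX}, columns =
#'   \code{panelY}).
#' @export
correlationMatrix <- function(expression, panelX, panelY,
                              logRouting = TRUE) {
  E <- asSampleMatrix(expression)
  unknown <- setdiff(c(panelX, panelY), colnames(E))
  if (length(unknown))
    stop("unknown gene name(s): ", paste(unknown, collapse = ", "))
  mk <- function() matrix(NA_real_, length(panelX), length(panelY),
                          dimnames = list(panelX, panelY))
  r <- mk(); p <- mk(); n <- mk()
  logged <- matrix(NA, length(panelX), length(panelY),
                   dimnames = list(panelX, panelY))
  for (i in panelX) for (j in panelY) {
    if (i == j) {
      r[i, j] <- 1; p[i, j] <- 0
      n[i, j] <- sum(is.finite(E[, i])); logged[i, j] <- FALSE
      next
    }
    res <- pearsonWithLogRouting(E[, i], E[, j], nameX = i, nameY = j,
                                 logRouting = logRouting)
    r[i, j] <- res@r; p[i, j] <- res@pValue; n[i, j] <- res@n
    logged[i, j] <- res@logX || res@logY
  }
  stars <- matrix(significanceStars(p), nrow(p), ncol(p),
                  dimnames = dimnames(p))
  methods::new("CorrelationMatrix", r = r, p = p, n = n, stars = stars,
               logged = logged)
}

#' Write a correlation matrix as a flat CSV
#'
#' One row per cell with r, p, effective n, stars and the log-routing
#' flag, in the row/column layout of a panel-by-panel correlation table.
#'
#' @param cm a [CorrelationMatrix-class].
#' @param file output CSV path.
#' @return the path, invisibly.
#' @export
writeCorrelationCsv <- function(cm, file) {
  write.csv(as.data.frame(cm), file, row.names = FALSE)
  invisible(file)
}
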