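# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic sub-seeds derived from one base seed; kept within 32-bit
# integer range.
deriveSeeds <- function(seed, n) {
  withSeed(seed, sample.int(.Machine$integer.max - 1L, n))
}

#' Repair a user-specified correlation matrix to positive semidefiniteness
#'
#' User-chosen pairwise correlation targets are often slightly inconsistent
#' (not jointly realisable). Eigenvalues in \code{[-tol, threshold]} are
#' clipped up to a small positive floor and the matrix is renormalised to a
#' unit diagonal. A matrix with an eigenvalue below \code{-tol} is rejected
#' as irreparably non-positive-semidefinite, naming the offending
#' eigenvalue.
#'
#' @param R symmetric matrix with unit diagonal.
#' @param tol largest tolerated negative eigenvalue magnitude before
#'   rejection (default 1e-6).
#' @param floor value small eigenvalues are clipped to (default 1e-8).
#' @return a positive-semidefinite correlation matrix with unit diagonal;
#'   equal to \code{R} when no repair was needed.
#' @examples
#' R <- diag(3)
#' R[1, 2] <- R[2, 1] <- 0.9
#' R[1, 3] <- R[3, 1] <- 0.9
#' R[2, 3] <- R[3, 2] <- -0.9   # jointly unrealisable
#' repairCorrelation(R)
#' @export
repairCorrelation <- function(R, tol = 1e-6, floor = 1e-8) {
  if (max(abs(R - t(R))) > 1e-8)
    stop("correlation matrix must be symmetric")
  e <- eigen((R + t(R)) / 2, symmetric = TRUE)
  lmin <- min(e$values)
  if (lmin < -tol)
    stop(sprintf(
      "correlation targets are not positive semidefinite: eigenvalue %.6g < -%g",
      lmin, tol))
  if (lmin >= floor) return(R)
  lam <- pmax(e$values, floor)
  R2 <- e$vectors %*% (lam * t(e$vectors))
  d <- sqrt(diag(R2))
  R2 <- R2 / tcrossprod(d)
  diag(R2) <- 1
  dimnames(R2) <- dimnames(R)
  R2
}

# Draw n rows from MVN(mu, diag(sd) %*% R %*% diag(sd)) via the eigen
# factorisation of R (handles semidefinite R, e.g. zero-SD variables).
rmvnormLatent <- function(n, R, mu = 0, sd = 1) {
  p <- ncol(R)
  e <- eigen((R + t(R)) / 2, symmetric = TRUE)
  lam <- pmax(e$values, 0)
  Z <- matrix(rnorm(n * p), n, p)
  X <- Z %*% (t(e$vectors) * sqrt(lam))
  X <- sweep(X, 2, rep_len(sd, p), "*")
  X <- sweep(X, 2, rep_len(mu, p), "+")
  colnames(X) <- colnames(R)
  X
}

# Significance stars mirroring the convention used for correlation tables:
# * < 0.05, ** < 0.01, *** < 0.001, **** < 0.0001.
significanceStars <- function(p) {
  s <- character(length(p))
  s[p < 0.05] <- "*"
  s[p < 0.01] <- "**"
  s[p < 0.001] <- "***"
  s[p < 0.0001] <- "****"
  s[is.na(p)] <- NA_character_
  s
}

# Coerce the expression container to a samples x variables numeric matrix.
# Accepts a SummarizedExperiment (genes x samples assay) or a matrix /
# data.frame already in samples x genes orientation.
asSampleMatrix <- function(x) {
  if (methods::is(x, "SummarizedExperiment")) {
    t(SummarizedExperiment::assay(x))
  } else if (is.data.frame(x)) {
    sid <- x[["sample_id"]]
    m <- as.matrix(x[, setdiff(colnames(x), "sample_id"), drop = FALSE])
    if (!is.null(sid)) rownames(m) <- sid
    storage.mode(m) <- "double"
    m
  } else {
    storage.mode(x) <- "double"
    x
  }
}
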