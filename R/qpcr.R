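#' Collapse replicate Ct measurements
#'
#' Averages replicate cycle-threshold values per sample and gene and flags
#' sample/gene combinations whose replicate range exceeds 0.5 Ct as
#' discordant (flagged, never dropped).
#'
#' @param ct long-format data.frame with columns \code{sample_id},
#'   \code{gene}, \code{replicate}, \code{ct}.
#' @param discordanceCt replicate range (cycles) above which a combination
#'   is flagged (default 0.5).
#' @return data.frame with one row per sample x gene: \code{sample_id},
#'   \code{gene}, \code{ct} (replicate mean), \code{n_replicates},
#'   \code{discordant}.
#' @examples
#' ct <- data.frame(sample_id = "S1", gene = "UCP1", replicate = 1:2,
#'                  ct = c(20.0, 20.4))
#' collapseDuplicates(ct)
#' @export
collapseDuplicates <- function(ct, discordanceCt = 0.5) {
  need <- c("sample_id", "gene", "ct")
  if (!all(need %in% names(ct)))
    stop("ct table needs columns sample_id, gene, ct")
  if (nrow(ct) == 0L) stop("ct table has no rows")
  if (any(!is.finite(ct$ct)) || any(ct$ct <= 0 | ct$ct >= 45))
    stop("Ct values must be finite and in (0, 45)")
  key <- interaction(ct$sample_id, ct$gene, drop = TRUE)
  agg <- do.call(rbind, lapply(split(seq_len(nrow(ct)), key), function(i) {
    v <- ct$ct[i]
    data.frame(sample_id = ct$sample_id[i[1]], gene = ct$gene[i[1]],
               ct = mean(v), n_replicates = length(v),
               discordant = (max(v) - min(v)) > discordanceCt,
               stringsAsFactors = FALSE)
  }))
  rownames(agg) <- NULL
  agg[order(agg$sample_id, agg$gene), , drop = FALSE]
}

#' Housekeeping-normalised relative expression from Ct values
#'
#' Standard single-reference delta-Ct quantification at perfect
#' amplification efficiency: \code{2^-(Ct_gene - Ct_housekeeping)}.
#'
#' @param ctGene,ctHousekeeping finite cycle-threshold values; vectorised.
#' @return relative expression (dimensionless, > 0).
#' @examples
#' relativeExpression(25, 20)  # 2^-5 = 0.03125
#' relativeExpression(18, 20)  # 4
#' @export
relativeExpression <- function(ctGene, ctHousekeeping) {
  if (any(!is.finite(ctGene)) || any(!is.finite(ctHousekeeping)))
    stop("Ct values must be finite")
  2^(-(ctGene - ctHousekeeping))
}

#' Quantify a Ct table into an expression matrix
#'
#' Collapses duplicates, then normalises every gene to the housekeeping
#' gene within each sample via [relativeExpression()]. Samples without a
#' housekeeping measurement are rejected.
#'
#' @param ct long-format Ct data.frame (see [collapseDuplicates()]).
#' @param housekeeping housekeeping gene name (default \code{"L19"}).
#' @return samples x genes matrix of relative expression (the
#'   housekeeping column is dropped).
#' @export
quantifyCtTable <- function(ct, housekeeping = "L19") {
  cc <- collapseDuplicates(ct)
  samples <- unique(cc$sample_id)
  hk <- cc[cc$gene == housekeeping, ]
  missing <- setdiff(samples, hk$sample_id)
  if (length(missing))
    stop("missing housekeeping (", housekeeping, ") Ct for sample(s): ",
         paste(missing, collapse = ", "))
  genes <- setdiff(unique(cc$gene), housekeeping)
  hkCt <- setNames(hk$ct, hk$sample_id)
  E <- matrix(NA_real_, length(samples), length(genes),
              dimnames = list(samples, genes))
  gg <- cc[cc$gene != housekeeping, ]
  E[cbind(match(gg$sample_id, samples), match(gg$gene, genes))] <-
    relativeExpression(gg$ct, hkCt[gg$sample_id])
  E
}

#' Fold change relative to a reference group
#'
#' Divides every expression value by the reference group's mean for that
#' gene, so the reference group's mean fold change is 1 by construction
#' (the calibrator step of a delta-delta-Ct analysis).
#'
#' @param expression samples x genes matrix (or cohort
#'   SummarizedExperiment).
#' @param groups group label per sample.
#' @param reference the reference (control) group label.
#' @return samples x genes matrix of fold changes.
#' @export
foldChange <- function(expression, groups, reference) {
  E <- asSampleMatrix(expression)
  if (length(groups) != nrow(E))
    stop("groups must have one label per sample")
  if (!reference %in% groups)
    stop("reference group '", reference, "' is empty")
  refMean <- colMeans(E[groups == reference, , drop = FALSE])
  if (any(refMean == 0))
    stop("reference group mean is zero for gene(s): ",
         paste(colnames(E)[refMean == 0], collapse = ", "))
  sweep(E, 2, refMean, "/")
}
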