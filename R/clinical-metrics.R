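#' Homeostatic model assessment of insulin resistance (HOMA-IR)
#'
#' \code{HOMA-IR = fasting glucose (mmol/L) x fasting insulin (mIU/L) / 22.5}.
#'
#' @param glucose fasting glucose in mmol/L (>= 0).
#' @param insulin fasting insulin in mIU/L (>= 0).
#' @return dimensionless index; vectorised.
#' @examples
#' homaIR(5.0, 10.0)   # 2.222...
#' homaIR(22.5, 1.0)   # 1
#' @export
homaIR <- function(glucose, insulin) {
  if (any(glucose < 0, na.rm = TRUE) || any(insulin < 0, na.rm = TRUE))
    stop("glucose and insulin must be >= 0")
  glucose * insulin / 22.5
}

#' Convert insulin from pmol/L to mIU/L
#'
#' The cohort table reports insulin in pmol/L while HOMA-IR requires
#' mIU/L; the standard clinical conversion is 6.945 pmol/L per mIU/L.
#'
#' @param insulinPmol insulin in pmol/L (>= 0).
#' @return insulin in mIU/L.
#' @examples
#' insulinPmolToMIU(6.945)  # 1
#' @export
insulinPmolToMIU <- function(insulinPmol) {
  if (any(insulinPmol < 0, na.rm = TRUE))
    stop("insulin must be >= 0")
  insulinPmol / 6.945
}

#' Friedewald estimate of LDL cholesterol
#'
#' \code{LDL = TC - HDL - TG / 2.2} (all mmol/L). The estimate is invalid
#' at high triglycerides; inputs with TG > 4.5 mmol/L are rejected. A
#' negative result is returned but flagged with a warning.
#'
#' @param totalCholesterol,hdl,tg serum lipids in mmol/L (>= 0).
#' @return LDL cholesterol in mmol/L; vectorised.
#' @examples
#' friedewaldLDL(5.2, 1.2, 2.2)  # 3
#' @export
friedewaldLDL <- function(totalCholesterol, hdl, tg) {
  if (any(totalCholesterol < 0, na.rm = TRUE) ||
      any(hdl < 0, na.rm = TRUE) || any(tg < 0, na.rm = TRUE))
    stop("lipid concentrations must be >= 0")
  if (any(tg > 4.5, na.rm = TRUE))
    stop("Friedewald estimate is not valid for TG > 4.5 mmol/L")
  ldl <- totalCholesterol - hdl - tg / 2.2
  if (any(ldl < 0, na.rm = TRUE))
    warning("negative LDL estimate returned; check input lipids")
  ldl
}

#' Percent excess weight loss after bariatric surgery
#'
#' \code{\%EWL = (preoperative weight - postoperative weight) /
#' (preoperative weight - ideal body weight) x 100}.
#'
#' @param weightPre,weightPost,idealWeight weights in kg; the preoperative
#'   weight must exceed the ideal weight (positive excess).
#' @return percent excess weight loss; vectorised.
#' @examples
#' percentExcessWeightLoss(120, 100, 70)  # 40
#' @export
percentExcessWeightLoss <- function(weightPre, weightPost, idealWeight) {
  if (any(weightPre <= idealWeight, na.rm = TRUE))
    stop("preoperative weight must exceed ideal weight (no excess to lose)")
  (weightPre - weightPost) / (weightPre - idealWeight) * 100
}

#' Append derived clinical indices to a clinical table
#'
#' Batch mode over a clinical table (data.frame or CSV path): appends
#' \code{insulin_miu} (from pmol/L), \code{homa_ir},
#' \code{ldl_friedewald}, and, when pre/post weights are present,
#' \code{pct_ewl}. Rows violating a formula's validity bound get
#' \code{NA} in that column rather than failing the batch.
#'
#' @param clinical data.frame (or path to a CSV) with columns
#'   \code{glucose}, \code{insulin} (pmol/L), \code{total_cholesterol},
#'   \code{hdl}, \code{tg}, optionally \code{weight_pre},
#'   \code{weight_post}, \code{ideal_weight}.
#' @param outFile optional path; when given the augmented table is also
#'   written as CSV.
#' @return the augmented data.frame (invisibly when \code{outFile} is
#'   given).
#' @export
addClinicalIndices <- function(clinical, outFile = NULL) {
  df <- if (is.character(clinical)) read.csv(clinical) else clinical
  guard <- function(expr) tryCatch(expr, error = function(e) NA_real_)
  if (!is.null(df$insulin)) {
    df$insulin_miu <- vapply(df$insulin,
      function(v) guard(insulinPmolToMIU(v)), numeric(1))
    if (!is.null(df$glucose))
      df$homa_ir <- vapply(seq_len(nrow(df)),
        function(i) guard(homaIR(df$glucose[i], df$insulin_miu[i])),
        numeric(1))
  }
  if (all(c("total_cholesterol", "hdl", "tg") %in% names(df)))
    df$ldl_friedewald <- vapply(seq_len(nrow(df)),
      function(i) guard(suppressWarnings(
        friedewaldLDL(df$total_cholesterol[i], df$hdl[i], df$tg[i]))),
      numeric(1))
  if (all(c("weight_pre", "weight_post", "ideal_weight") %in% names(df)))
    df$pct_ewl <- vapply(seq_len(nrow(df)),
      function(i) guard(percentExcessWeightLoss(
        df$weight_pre[i], df$weight_post[i], df$ideal_weight[i])),
      numeric(1))
  if (!is.null(outFile)) {
    write.csv(df, outFile, row.names = FALSE)
    return(invisible(df))
  }
  df
}
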