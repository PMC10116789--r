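# Normality-routed hypothesis testing: every comparison is dispatched to a
# parametric or non-parametric branch by the D'Agostino-Pearson omnibus
# test combined with skewness/kurtosis z-value bounds.

# D'Agostino (1970) transformed skewness z statistic.
dagostinoSkewZ <- function(x) {
  n <- length(x)
  m <- mean(x)
  m2 <- mean((x - m)^2); m3 <- mean((x - m)^3)
  b1 <- m3 / m2^1.5
  Y <- b1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  W2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(log(sqrt(W2)))
  alpha <- sqrt(2 / (W2 - 1))
  delta * log(Y / alpha + sqrt((Y / alpha)^2 + 1))
}

# Anscombe-Glynn (1983) transformed kurtosis z statistic.
anscombeKurtZ <- function(x) {
  n <- length(x)
  m <- mean(x)
  m2 <- mean((x - m)^2); m4 <- mean((x - m)^4)
  b2 <- m4 / m2^2
  E <- 3 * (n - 1) / (n + 1)
  v <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xs <- (b2 - E) / sqrt(v)
  beta1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  A <- 6 + 8 / beta1 * (2 / beta1 + sqrt(1 + 4 / beta1^2))
  ((1 - 2 / (9 * A)) -
     ((1 - 2 / A) / (1 + xs * sqrt(2 / (A - 4))))^(1/3)) /
    sqrt(2 / (9 * A))
}

#' D'Agostino-Pearson omnibus normality test
#'
#' Combines the transformed skewness z (D'Agostino) and kurtosis z
#' (Anscombe-Glynn) into \eqn{K^2 = z_s^2 + z_k^2}, referred to a
#' chi-squared distribution with 2 df.
#'
#' @param x numeric vector, n >= 8, non-constant.
#' @return list with \code{statistic} (K2), \code{p_value},
#'   \code{z_skewness}, \code{z_kurtosis}.
#' @export
dagostinoPearson <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 8L)
    stop("D'Agostino-Pearson omnibus test needs n >= 8")
  if (var(x) == 0) stop("constant vector")
  zs <- dagostinoSkewZ(x)
  zk <- anscombeKurtZ(x)
  k2 <- zs^2 + zk^2
  list(statistic = k2,
       p_value = pchisq(k2, df = 2, lower.tail = FALSE),
       z_skewness = zs, z_kurtosis = zk)
}

#' Route a vector to the parametric or non-parametric branch
#'
#' A vector is treated as parametric when the D'Agostino-Pearson omnibus
#' p-value is >= 0.05 AND both the skewness and kurtosis z-values lie
#' inside (-1.96, 1.96). Vectors too short for the omnibus test (n < 8) or
#' constant vectors are routed non-parametric with a warning rather than
#' an error.
#'
#' @param values numeric vector.
#' @return list with \code{branch} (\code{"parametric"} /
#'   \code{"nonparametric"}), \code{p_value}, \code{z_skewness},
#'   \code{z_kurtosis}, \code{note}.
#' @examples
#' assessNormality(rnorm(200))$branch
#' @export
assessNormality <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 8L) {
    warning("n < 8: too few observations for the normality omnibus; ",
            "routing nonparametric")
    return(list(branch = "nonparametric", p_value = NA_real_,
                z_skewness = NA_real_, z_kurtosis = NA_real_,
                note = "n < 8"))
  }
  if (var(values) == 0) {
    warning("constant vector: routing nonparametric")
    return(list(branch = "nonparametric", p_value = NA_real_,
                z_skewness = NA_real_, z_kurtosis = NA_real_,
                note = "constant"))
  }
  dp <- dagostinoPearson(values)
  ok <- dp$p_value >= 0.05 &&
    abs(dp$z_skewness) < 1.96 && abs(dp$z_kurtosis) < 1.96
  list(branch = if (ok) "parametric" else "nonparametric",
       p_value = dp$p_value, z_skewness = dp$z_skewness,
       z_kurtosis = dp$z_kurtosis, note = "")
}

# Dunn's rank-based post hoc after Kruskal-Wallis, with a tie correction;
# unadjusted and Bonferroni-adjusted two-sided p-values are both reported.
dunnPosthoc <- function(values, groups) {
  g <- factor(groups)
  N <- length(values)
  rk <- rank(values)
  meanRank <- tapply(rk, g, mean)
  n <- tapply(rk, g, length)
  ties <- table(rk)
  tieCorr <- sum(ties^3 - ties) / (12 * (N - 1))
  lev <- levels(g)
  pairs <- utils::combn(lev, 2)
  out <- data.frame(
    group1 = pairs[1, ], group2 = pairs[2, ],
    z = NA_real_, p_value = NA_real_, p_adjusted = NA_real_,
    stringsAsFactors = FALSE)
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1, k]; j <- pairs[2, k]
    se <- sqrt((N * (N + 1) / 12 - tieCorr) * (1 / n[[i]] + 1 / n[[j]]))
    z <- (meanRank[[i]] - meanRank[[j]]) / se
    out$z[k] <- z
    out$p_value[k] <- 2 * pnorm(-abs(z))
  }
  out$p_adjusted <- pmin(1, out$p_value * ncol(pairs))
  out
}

tukeyPosthocTable <- function(fit, term) {
  tk <- TukeyHSD(fit)[[term]]
  pairs <- strsplit(rownames(tk), "-", fixed = TRUE)
  data.frame(
    group1 = vapply(pairs, `[`, "", 1L),
    group2 = vapply(pairs, `[`, "", 2L),
    diff = tk[, "diff"], p_adjusted = tk[, "p adj"],
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Compare three or more groups with normality-routed tests
#'
#' Routes on the pooled within-group residuals via [assessNormality()]:
#' the parametric branch runs one-way ANOVA followed by Tukey's HSD, the
#' non-parametric branch runs the Kruskal-Wallis test followed by Dunn's
#' multiple-comparison test.
#'
#' @param values numeric response vector.
#' @param groups group label per value; at least 3 non-empty levels, each
#'   with n >= 2.
#' @return a [StatResult-class] with omnibus statistic/p, branch, per-group
#'   n, and the matched post-hoc table.
#' @examples
#' set.seed(1)
#' res <- compareGroups(rnorm(60), rep(c("a", "b", "c"), each = 20))
#' branch(res); pValue(res)
#' @export
compareGroups <- function(values, groups) {
  keep <- is.finite(values) & !is.na(groups)
  values <- values[keep]; g <- factor(as.character(groups[keep]))
  n <- table(g)
  if (any(n == 0L)) stop("empty group(s): ",
                         paste(names(n)[n == 0L], collapse = ", "))
  if (nlevels(g) < 3L)
    stop("fewer than 3 groups: use comparePaired() or a two-group test")
  if (any(n < 2L)) stop("every group needs n >= 2")
  resid <- values - ave(values, g)
  rt <- withCallingHandlers(
    assessNormality(resid),
    warning = function(w) invokeRestart("muffleWarning"))
  notes <- if (nzchar(rt$note)) paste("normality routing:", rt$note)
           else character()
  if (rt$branch == "parametric") {
    fit <- aov(values ~ g)
    sm <- summary(fit)[[1]]
    res <- methods::new("StatResult",
      testName = "one-way ANOVA + Tukey HSD",
      statistic = c(F = sm[["F value"]][1]),
      pValue = c(omnibus = sm[["Pr(>F)"]][1]),
      nPerGroup = setNames(as.integer(n), names(n)),
      branch = "parametric",
      posthoc = tukeyPosthocTable(fit, "g"),
      notes = notes)
  } else {
    kw <- kruskal.test(values, g)
    res <- methods::new("StatResult",
      testName = "Kruskal-Wallis + Dunn",
      statistic = c(H = unname(kw$statistic)),
      pValue = c(omnibus = kw$p.value),
      nPerGroup = setNames(as.integer(n), names(n)),
      branch = "nonparametric",
      posthoc = dunnPosthoc(values, g),
      notes = notes)
  }
  res
}

#' Paired pre/post comparison with normality-routed tests
#'
#' Routes on the distribution of the paired differences: paired two-tailed
#' t-test if parametric, Wilcoxon signed-rank test if non-parametric.
#' All-zero differences return p = 1 by convention, with a warning.
#'
#' @param pre,post equal-length numeric vectors paired by position,
#'   n >= 3.
#' @return a [StatResult-class]; the post-hoc slot is empty (no omnibus
#'   over >= 3 groups is involved).
#' @examples
#' comparePaired(c(1, 2, 3, 4, 5, 6), c(2, 3, 5, 5, 7, 8))
#' @export
comparePaired <- function(pre, post) {
  if (length(pre) != length(post))
    stop("pre and post must have equal length")
  keep <- is.finite(pre) & is.finite(post)
  pre <- pre[keep]; post <- post[keep]
  n <- length(pre)
  if (n < 3L) stop("paired comparison needs n >= 3 complete pairs")
  d <- post - pre
  empty <- data.frame()
  if (all(d == 0)) {
    warning("all paired differences are zero; returning p = 1")
    return(methods::new("StatResult",
      testName = "paired comparison (degenerate)",
      statistic = c(statistic = 0), pValue = c(omnibus = 1),
      nPerGroup = c(pairs = n), branch = "nonparametric",
      posthoc = empty, notes = "all differences zero"))
  }
  rt <- withCallingHandlers(
    assessNormality(d),
    warning = function(w) invokeRestart("muffleWarning"))
  notes <- if (nzchar(rt$note)) paste("normality routing:", rt$note)
           else character()
  if (rt$branch == "parametric") {
    tt <- t.test(post, pre, paired = TRUE)
    methods::new("StatResult",
      testName = "paired t-test (two-tailed)",
      statistic = c(t = unname(tt$statistic)),
      pValue = c(omnibus = tt$p.value),
      nPerGroup = c(pairs = n), branch = "parametric",
      posthoc = empty, notes = notes)
  } else {
    wt <- suppressWarnings(wilcox.test(post, pre, paired = TRUE))
    methods::new("StatResult",
      testName = "Wilcoxon signed-rank test",
      statistic = c(V = unname(wt$statistic)),
      pValue = c(omnibus = wt$p.value),
      nPerGroup = c(pairs = n), branch = "nonparametric",
      posthoc = empty, notes = notes)
  }
}

#' Two-way factorial ANOVA with Tukey post hoc
#'
#' Main effects and interaction via type-II sums of squares (robust to
#' mildly unbalanced designs), followed by Tukey's multiple-comparison
#' test across the factor-combination cell means. The branch is always
#' parametric: factorial treatment designs are analysed by two-way ANOVA
#' unconditionally.
#'
#' @param values numeric response.
#' @param factorA,factorB factor labels; >= 2 levels each and every
#'   cell of the design non-empty.
#' @return a [StatResult-class] with statistics/p-values named
#'   \code{factorA}, \code{factorB}, \code{interaction}.
#' @export
twoWayAnova <- function(values, factorA, factorB) {
  keep <- is.finite(values)
  values <- values[keep]
  a <- factor(as.character(factorA[keep]))
  b <- factor(as.character(factorB[keep]))
  if (nlevels(a) < 2L || nlevels(b) < 2L)
    stop("both factors need at least 2 levels")
  if (any(table(a, b) == 0L))
    stop("empty design cell(s): unbalanced designs with empty cells are ",
         "unsupported")
  fit <- lm(values ~ a * b)
  an <- car::Anova(fit, type = 2)
  stat <- c(factorA = an[["F value"]][1], factorB = an[["F value"]][2],
            interaction = an[["F value"]][3])
  pv <- c(factorA = an[["Pr(>F)"]][1], factorB = an[["Pr(>F)"]][2],
          interaction = an[["Pr(>F)"]][3])
  cell <- factor(paste(a, b, sep = ":"))
  cellFit <- aov(values ~ cell)
  nPer <- table(cell)
  methods::new("StatResult",
    testName = "two-way ANOVA (type II) + Tukey HSD on cell means",
    statistic = stat, pValue = pv,
    nPerGroup = setNames(as.integer(nPer), names(nPer)),
    branch = "parametric",
    posthoc = tukeyPosthocTable(cellFit, "cell"),
    notes = character())
}
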