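test_that("generation is deterministic and respects the design counts", {
  cfg <- smallConfig(seed = 41)
  se1 <- generateCohort(cfg)
  se2 <- generateCohort(cfg)
  expect_identical(expressionTable(se1), expressionTable(se2))
  expect_identical(clinicalTable(se1), clinicalTable(se2))
  expect_equal(ncol(se1), 45L)
  expect_equal(as.integer(table(clinicalTable(se1)$group)[c("lean",
    "overweight", "obese")]), c(15L, 15L, 15L))
  pe1 <- generatePaired(cfg)
  pe2 <- generatePaired(cfg)
  expect_identical(expressionTable(pe1), expressionTable(pe2))
  expect_equal(ncol(pe1), 2L * cfg@nPaired)
})

test_that("expression is strictly positive and concentrations non-negative", {
  cfg <- smallConfig(seed = 42)
  se <- generateCohort(cfg)
  expect_true(all(expressionTable(se) > 0))
  clin <- clinicalTable(se)
  for (v in cfg@covariateNames) expect_true(all(clin[[v]] >= 0))
  pe <- generatePaired(cfg)
  expect_true(all(expressionTable(pe) > 0))
})

test_that("zero-structure configurations give independent variables", {
  cfg <- independentConfig(2000L, seed = 43)
  se <- generateCohort(cfg)
  E <- log(expressionTable(se))
  C <- cor(E)
  offdiag <- abs(C[upper.tri(C)])
  expect_lt(max(offdiag), 0.1)
})

test_that("planted gene-covariate correlation is recovered at large n", {
  cfg0 <- syntheticConfig(seed = 44)
  R <- cfg0@targetCorrelation
  shifts <- cfg0@groupShifts; shifts[] <- 0
  cfg <- syntheticConfig(nLean = 5000L, nOverweight = 0L, nObese = 0L,
                         targetCorrelation = R, groupShifts = shifts,
                         seed = 44)
  se <- generateCohort(cfg)
  r <- cor(log(expressionTable(se)[, "CIDEA"]),
           clinicalTable(se)$bmi)
  expect_lt(abs(r - (-0.4)), 0.03)
})

test_that("correlation targets must be repairable", {
  cfg <- smallConfig(seed = 45)
  R <- cfg@targetCorrelation
  # force a badly inconsistent triple -> strongly negative eigenvalue
  R["UCP1", "PGC1A"] <- R["PGC1A", "UCP1"] <- 0.95
  R["UCP1", "CIDEA"] <- R["CIDEA", "UCP1"] <- 0.95
  R["PGC1A", "CIDEA"] <- R["CIDEA", "PGC1A"] <- -0.95
  expect_error(repairCorrelation(R), "eigenvalue")
  # mildly inconsistent targets are repaired to PSD with unit diagonal
  R2 <- cfg@targetCorrelation
  R2["UCP1", "PGC1A"] <- R2["PGC1A", "UCP1"] <- 0.9
  R2["UCP1", "CIDEA"] <- R2["CIDEA", "UCP1"] <- 0.9
  R2["PGC1A", "CIDEA"] <- R2["CIDEA", "PGC1A"] <- 0.65
  rep <- repairCorrelation(R2)
  expect_gte(min(eigen(rep, symmetric = TRUE)$values), 0)
  expect_equal(unname(diag(rep)), rep(1, nrow(rep)), tolerance = 1e-12)
})

test_that("config invariants are enforced", {
  expect_error(syntheticConfig(noiseSd = 0), "positive")
  expect_error(syntheticConfig(nLean = -1L), ">= 0")
  cfg <- smallConfig()
  A <- cfg@plantedNetwork
  diag(A) <- 1
  expect_error(syntheticConfig(plantedNetwork = A), "zero diagonal")
})

test_that("null surgery effect produces centred paired deltas", {
  cfg0 <- syntheticConfig(seed = 46)
  zeroEffect <- cfg0@surgeryEffect * 0
  cfg <- syntheticConfig(nPaired = 200L, surgeryEffect = zeroEffect,
                         seed = 46)
  pe <- generatePaired(cfg)
  cd <- clinicalTable(pe)
  tp <- cd$timepoint
  for (v in c("endotoxin", "glucose", "bmi")) {
    d <- cd[[v]][tp == "post"] - cd[[v]][tp == "pre"]
    expect_lt(abs(mean(d)), 2 * sd(d) / sqrt(length(d)) + 1e-12)
  }
})

test_that("default surgery effects move endotoxin down and BAT genes up", {
  cfg <- syntheticConfig(nPaired = 300L, seed = 47)
  pe <- generatePaired(cfg)
  cd <- clinicalTable(pe)
  tp <- cd$timepoint
  dEndo <- cd$endotoxin[tp == "post"] - cd$endotoxin[tp == "pre"]
  expect_lt(mean(dEndo), 0)
  E <- expressionTable(pe)
  dCidea <- E[tp == "post", "CIDEA"] - E[tp == "pre", "CIDEA"]
  expect_gt(mean(dCidea), 0)
  res <- comparePaired(cd$endotoxin[tp == "pre"],
                       cd$endotoxin[tp == "post"])
  expect_lt(unname(pValue(res)["omnibus"]), 0.001)
})

test_that("paired generation needs at least 3 subjects", {
  expect_error(generatePaired(syntheticConfig(nPaired = 2L)),
               "nPaired >= 3")
})

test_that("Ct plates follow the delta-Ct identity and reject bad input", {
  E <- matrix(c(1.0, 0.03125), 1, 2,
              dimnames = list("S1", c("g1", "g2")))
  ct <- generateCtPlates(E, noiseSd = 0, seed = 1)
  cc <- collapseDuplicates(ct)
  hk <- cc$ct[cc$gene == "L19"]
  expect_equal(cc$ct[cc$gene == "g1"], hk, tolerance = 1e-12)
  expect_equal(cc$ct[cc$gene == "g2"] - hk, 5.0, tolerance = 1e-12)
  expect_equal(nrow(ct), 6L)  # 2 genes + housekeeping, in duplicate
  bad <- E; bad[1, 1] <- 0
  expect_error(generateCtPlates(bad), "strictly positive")
})

test_that("planted truth records the generating configuration", {
  cfg <- smallConfig(seed = 48)
  se <- generateCohort(cfg)
  truth <- plantedTruth(se)
  expect_s4_class(truth, "PlantedTruth")
  expect_identical(truth@seed, cfg@seed)
  expect_identical(truth@adjacency, cfg@plantedNetwork)
  expect_identical(truth@correlationTargets, cfg@targetCorrelation)
})

test_that("a planted linear network shapes the generated correlations", {
  cfg0 <- syntheticConfig(seed = 49)
  genes <- c(cfg0@batGenes, cfg0@inflammatoryGenes)
  vars <- c(genes, cfg0@covariateNames)
  R <- diag(length(vars)); dimnames(R) <- list(vars, vars)
  A <- matrix(0, length(genes), length(genes),
              dimnames = list(genes, genes))
  A["IL6", "UCP1"] <- -0.8
  shifts <- cfg0@groupShifts; shifts[] <- 0
  cfg <- syntheticConfig(nLean = 3000L, nOverweight = 0L, nObese = 0L,
                         targetCorrelation = R, plantedNetwork = A,
                         groupShifts = shifts, seed = 49)
  se <- generateCohort(cfg)
  E <- log(expressionTable(se))
  expect_lt(cor(E[, "IL6"], E[, "UCP1"]), -0.5)
  expect_lt(abs(cor(E[, "IL6"], E[, "MCP1"])), 0.08)
})
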