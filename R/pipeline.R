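# Orchestration: configuration, validation, stage dispatch, manifest.

#' Write a generated cohort as CSV files
#'
#' Expression (sample IDs in column 1), clinical table, and the planted
#' truth as JSON.
#'
#' @param se cohort or paired SummarizedExperiment.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix (default \code{"cohort"}).
#' @return character vector of the paths written.
#' @export
writeCohortCsv <- function(se, dir, prefix = "cohort") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  E <- expressionTable(se)
  exprFile <- file.path(dir, paste0(prefix, "_expression.csv"))
  clinFile <- file.path(dir, paste0(prefix, "_clinical.csv"))
  write.csv(data.frame(sample_id = rownames(E), E, check.names = FALSE),
            exprFile, row.names = FALSE)
  write.csv(clinicalTable(se), clinFile, row.names = FALSE)
  files <- c(exprFile, clinFile)
  truth <- plantedTruth(se)
  if (!is.null(truth)) {
    truthFile <- file.path(dir, paste0(prefix, "_truth.json"))
    jsonlite::write_json(
      list(adjacency = truth@adjacency,
           correlation_targets = truth@correlationTargets,
           group_effects = truth@groupEffects,
           surgery_effects = as.list(truth@surgeryEffects),
           seed = truth@seed),
      truthFile, digits = NA, auto_unbox = TRUE, matrix = "rowmajor")
    files <- c(files, truthFile)
  }
  files
}

#' Read expression and clinical CSV files into a SummarizedExperiment
#'
#' @param exprFile CSV with \code{sample_id} in column 1 and one column
#'   per gene.
#' @param clinFile CSV with \code{sample_id} plus clinical columns.
#' @return a [SummarizedExperiment::SummarizedExperiment] with assay
#'   \code{relexpr}.
#' @export
readCohortCsv <- function(exprFile, clinFile) {
  ed <- read.csv(exprFile, check.names = FALSE)
  cd <- read.csv(clinFile, check.names = FALSE)
  E <- as.matrix(ed[, -1, drop = FALSE])
  rownames(E) <- ed[[1]]
  cd <- cd[match(rownames(E), cd$sample_id), , drop = FALSE]
  SummarizedExperiment::SummarizedExperiment(
    assays = list(relexpr = t(E)),
    colData = S4Vectors::DataFrame(cd, row.names = rownames(E)))
}

#' Validate expression and clinical tables before analysis
#'
#' Report-only checks: sample-ID join completeness in both directions,
#' strict positivity of expression, group/timepoint label vocabulary
#' (\code{lean}, \code{overweight}, \code{obese}, \code{pre},
#' \code{post}), and duplicate sample IDs.
#'
#' @param expression samples x genes matrix or SummarizedExperiment.
#' @param clinical clinical data.frame with \code{sample_id}.
#' @return data.frame of violations (zero rows when the tables are
#'   clean), with columns \code{rule} and \code{message}.
#' @export
validateTables <- function(expression, clinical) {
  E <- asSampleMatrix(expression)
  v <- list()
  add <- function(rule, message)
    v[[length(v) + 1L]] <<- data.frame(rule = rule, message = message,
                                       stringsAsFactors = FALSE)
  exprIds <- rownames(E)
  clinIds <- as.character(clinical$sample_id)
  for (s in setdiff(exprIds, clinIds))
    add("join", paste0("expression sample '", s,
                       "' absent from clinical table"))
  for (s in setdiff(clinIds, exprIds))
    add("join", paste0("clinical sample '", s,
                       "' absent from expression table"))
  if (anyDuplicated(exprIds))
    add("duplicate_id", paste("duplicate expression sample IDs:",
        paste(unique(exprIds[duplicated(exprIds)]), collapse = ", ")))
  if (anyDuplicated(clinIds))
    add("duplicate_id", paste("duplicate clinical sample IDs:",
        paste(unique(clinIds[duplicated(clinIds)]), collapse = ", ")))
  neg <- which(E <= 0, arr.ind = TRUE)
  if (nrow(neg))
    for (k in seq_len(nrow(neg)))
      add("positivity", sprintf(
        "non-positive expression for sample '%s', gene '%s'",
        exprIds[neg[k, 1]], colnames(E)[neg[k, 2]]))
  vocab <- c("lean", "overweight", "obese", "pre", "post")
  for (col in intersect(c("group", "timepoint"), names(clinical))) {
    bad <- setdiff(unique(as.character(clinical[[col]])), vocab)
    for (b in bad)
      add("vocabulary", paste0("unknown ", col, " label '", b, "'"))
  }
  if (length(v)) do.call(rbind, v)
  else data.frame(rule = character(), message = character(),
                  stringsAsFactors = FALSE)
}

defaultStages <- c("simulate", "qpcr", "metrics", "stats",
                   "correlations", "anni")

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in dependency order on either a synthetic
#' cohort (generated in place from a seed) or user-supplied CSV tables:
#' qPCR quantification, clinical indices, normality-routed group
#' statistics, correlation matrices and paired delta correlations, and
#' ANN interaction inference with network export. Every output file is
#' listed, with its MD5 checksum, in a JSON manifest; the manifest
#' carries no timestamps, so identical configuration and seed yield
#' byte-identical outputs.
#'
#' @param config a named list (or path to a JSON file) with elements:
#'   \describe{
#'     \item{seed}{integer, mandatory.}
#'     \item{output_dir}{output directory.}
#'     \item{synthetic}{optional list of [syntheticConfig()] overrides;
#'       mutually exclusive with \code{input}.}
#'     \item{input}{optional list with \code{expression_csv},
#'       \code{clinical_csv}, optional \code{ct_csv}.}
#'     \item{stages}{character subset of \code{simulate}, \code{qpcr},
#'       \code{metrics}, \code{stats}, \code{correlations}, \code{anni};
#'       default all applicable.}
#'     \item{ann}{optional list of [annConfig()] overrides.}
#'     \item{anni_genes}{optional gene subset for the inference stage.}
#'     \item{include_covariates}{covariates appended as pseudo-genes for
#'       ANNi (default none).}
#'   }
#' @return the manifest, invisibly (list with \code{seed},
#'   \code{stages}, \code{files}, \code{warnings}).
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  if (is.null(config$seed)) stop("config$seed is mandatory")
  seed <- as.integer(config$seed)
  outDir <- config$output_dir %||% stop("config$output_dir is mandatory")
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  hasSynth <- !is.null(config$synthetic)
  hasInput <- !is.null(config$input)
  if (hasSynth && hasInput)
    stop("config must contain exactly one of 'synthetic' or 'input'")
  if (!hasSynth && !hasInput)
    stop("config must contain one of 'synthetic' or 'input'")
  stages <- config$stages %||% defaultStages
  bad <- setdiff(stages, defaultStages)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  if (hasInput) stages <- setdiff(stages, "simulate")

  files <- character()
  warningsSeen <- character()
  record <- function(f) files <<- c(files, f)
  runStage <- function(name, code) {
    tryCatch(
      withCallingHandlers(code, warning = function(w) {
        warningsSeen <<- c(warningsSeen,
                           paste0(name, ": ", conditionMessage(w)))
        invokeRestart("muffleWarning")
      }),
      error = function(e) stop("stage '", name, "' failed: ",
                               conditionMessage(e), call. = FALSE))
  }

  se <- NULL; pairedSe <- NULL
  if (hasSynth) {
    synthArgs <- config$synthetic
    synthArgs$seed <- synthArgs$seed %||% seed
    scfg <- do.call(syntheticConfig, synthArgs)
    if ("simulate" %in% stages) runStage("simulate", {
      se <- generateCohort(scfg)
      pairedSe <- generatePaired(scfg)
      record(writeCohortCsv(se, outDir, "cohort"))
      record(writeCohortCsv(pairedSe, outDir, "paired"))
    }) else {
      se <- generateCohort(scfg)
      pairedSe <- generatePaired(scfg)
    }
  } else {
    se <- readCohortCsv(config$input$expression_csv,
                        config$input$clinical_csv)
  }

  if ("qpcr" %in% stages && hasInput && !is.null(config$input$ct_csv))
    runStage("qpcr", {
      ct <- read.csv(config$input$ct_csv)
      E <- quantifyCtTable(ct, housekeeping = config$housekeeping %||%
                             "L19")
      f <- file.path(outDir, "quantified_expression.csv")
      write.csv(data.frame(sample_id = rownames(E), E,
                           check.names = FALSE), f, row.names = FALSE)
      record(f)
    })

  clin <- clinicalTable(se)
  if ("metrics" %in% stages) runStage("metrics", {
    f <- file.path(outDir, "clinical_with_indices.csv")
    addClinicalIndices(clin, outFile = f)
    record(f)
  })

  if ("stats" %in% stages && "group" %in% names(clin) &&
      length(unique(clin$group)) >= 3L) runStage("stats", {
    E <- expressionTable(se)
    rows <- lapply(colnames(E), function(g) {
      res <- compareGroups(E[, g], clin$group)
      data.frame(variable = g, test = res@testName,
                 branch = res@branch,
                 statistic = unname(res@statistic[1]),
                 p_value = unname(res@pValue[1]),
                 stringsAsFactors = FALSE)
    })
    f <- file.path(outDir, "group_stats.csv")
    write.csv(do.call(rbind, rows), f, row.names = FALSE)
    record(f)
  })

  if ("correlations" %in% stages) runStage("correlations", {
    E <- expressionTable(se)
    genes <- colnames(E)
    truth <- plantedTruth(se)
    cfgGenes <- if (hasSynth)
      list(bat = S4Vectors::metadata(se)$config@batGenes,
           infl = S4Vectors::metadata(se)$config@inflammatoryGenes)
    else list(bat = genes, infl = genes)
    cm <- correlationMatrix(se, cfgGenes$infl, cfgGenes$bat)
    f <- file.path(outDir, "correlation_matrix.csv")
    writeCorrelationCsv(cm, f)
    record(f)
    if (!is.null(pairedSe)) {
      bat <- cfgGenes$bat
      rows <- lapply(bat, function(g) {
        res <- deltaCorrelation(pairedSe, "endotoxin", g)
        data.frame(variable_x = "delta_endotoxin",
                   variable_y = paste0("delta_", g),
                   r = res@r, p_value = res@pValue, n = res@n,
                   stringsAsFactors = FALSE)
      })
      f2 <- file.path(outDir, "delta_correlations.csv")
      write.csv(do.call(rbind, rows), f2, row.names = FALSE)
      record(f2)
    }
  })

  if ("anni" %in% stages) runStage("anni", {
    annArgs <- config$ann %||% list()
    annArgs$seed <- annArgs$seed %||% seed
    acfg <- do.call(annConfig, annArgs)
    sub <- se
    if (!is.null(config$anni_genes))
      sub <- se[intersect(rownames(se), config$anni_genes), ]
    im <- interactionMatrix(sub, acfg,
      includeCovariates = config$include_covariates)
    mf <- file.path(outDir, "interaction_matrix.csv")
    inf <- file.path(outDir, "influence_summary.csv")
    writeInteractionCsv(im, mf, inf)
    record(c(mf, inf))
    edges <- rankInteractions(im)
    sif <- file.path(outDir, "network.sif")
    exportNetwork(edges, sif, "sif")
    record(c(sif, file.path(outDir, "network_edges.csv")))
    gml <- file.path(outDir, "network.graphml")
    exportNetwork(edges, gml, "graphml")
    record(gml)
  })

  manifest <- list(
    seed = seed,
    stages = as.list(stages),
    config = config[setdiff(names(config), "output_dir")],
    files = lapply(files, function(f)
      list(path = basename(f), md5 = unname(tools::md5sum(f)))),
    warnings = as.list(warningsSeen))
  manifestFile <- file.path(outDir, "manifest.json")
  jsonlite::write_json(manifest, manifestFile, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}
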