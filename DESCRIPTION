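Package: anniNet
Title: Neural-Network Inference of Signed Gene-Interaction Networks with
    Cohort Statistics for Adipose Browning Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Artificial neural network inference (ANNi) of signed
    gene-gene influence networks from relative-expression panels:
    per-target single-hidden-layer models trained under Monte Carlo
    cross-validation, composite input-to-output prediction weights
    averaged into a signed interaction matrix, collapsed into
    influence-exerted and influence-received summaries, and exported as
    Cytoscape-readable SIF and GraphML. The inference engine is embedded
    in the statistical workflow of an adipocyte-browning/endotoxaemia
    cohort study: normality-routed group comparisons (one-way ANOVA with
    Tukey or Kruskal-Wallis with Dunn), paired pre/post-intervention
    tests, log-routed Pearson correlation matrices and delta
    correlations, qPCR delta-Ct quantification against a housekeeping
    gene, and closed-form clinical indices (HOMA-IR, Friedewald LDL,
    percent excess weight loss). A synthetic cohort generator with
    planted correlation structure and a planted signed network provides
    ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    car,
    xml2
Suggests:
    testthat (>= 3.0.0),
    nnet,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
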