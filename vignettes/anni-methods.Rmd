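---
title: "Neural-network inference of signed gene-interaction networks: methods and design"
author: "anniNet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Neural-network inference of signed gene-interaction networks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anniNet)
library(SummarizedExperiment)
```

## The scientific problem

Obesity is accompanied by metabolic endotoxaemia — elevated circulating
lipopolysaccharide (LPS) from gut-derived bacteria — and by low-grade
adipose-tissue inflammation. Both are suspected to suppress the "browning"
of white adipose tissue, i.e. the appearance of BRITE/beige adipocytes
marked by UCP1, PGC1A, CIDEA, ELOVL3, PLIN5 and SLC27A2 expression.
Cross-sectional cohorts stratified by BMI, and paired pre/post-bariatric
surgery designs, yield relative-expression panels (qPCR, normalised to the
L19 housekeeping gene) together with clinical covariates (BMI, serum
endotoxin, glucose, insulin, lipids).

anniNet implements the computational side of such a study as a tested,
reusable pipeline: the ANNi engine that infers a signed gene-interaction
network from expression panels with small neural models, embedded in the
surrounding statistical workflow (normality-routed group tests, paired
analyses, log-routed Pearson correlations, clinical indices), exercised
end-to-end on a synthetic cohort generator that carries its own ground
truth.

## The ANNi model

For every target variable $j$ in a panel of $p$ variables, a
single-hidden-layer feed-forward network predicts $x_j$ from all other
variables:

$$\hat{x}_j = b_2 + \sum_{h=1}^{H} w^{(2)}_{h}\,
  \sigma\!\Big(b_{1h} + \sum_{i \ne j} w^{(1)}_{ih}\, x_i\Big),$$

with sigmoidal hidden units ($H = 3$ by default) and a linear output.
Each model is trained under Monte Carlo cross-validation: `mcResamples`
(default 50) random 60/20/20 train/validation/test splits, full-batch
gradient descent with momentum, early stopping on the validation error,
and min-max scaling fitted on the training fraction only (no information
leaks from validation or test samples into the scaling).

The signed influence of variable $i$ on target $j$ in one fitted model is
the composite prediction weight

$$w_{i \to j} = \sum_{h=1}^{H} w^{(1)}_{ih}\, w^{(2)}_{h},$$

the standard connection-weights statistic: it preserves sign (a net
negative path means higher $x_i$ predicts lower $x_j$) and sums the
contribution of every hidden unit. Entries are averaged across resamples
into the interaction matrix $W$, with their across-resample standard
deviation kept as a dispersion matrix; $W_{jj} = 0$ structurally.

$W$ is *collapsed* by summing values from and to each gene: row sums give
the influence a gene exerts, column sums the influence it receives. Both
totals equal the grand sum of $W$ (exactly in exact arithmetic; in
floating point they agree to summation order, i.e. ~1e-15 relative).
Ranks are assigned on the signed sums, rank 1 being the most negative
(most suppressive) gene, ties broken by gene-name lexical order so
results are deterministic.

### What the influence score can and cannot identify

The composite-weight score is near-symmetric: if $x_i$ predicts $x_j$,
then $x_j$ also predicts $x_i$, and both orientations of a dependence
receive high $|W|$. Cross-sectional expression data carry no information
to orient an edge. We therefore evaluate top-$k$ recovery at the level of
unordered gene pairs ([edgeRecovery()]), while the exported network keeps
both directed entries with their own weights. Pre/post designs can be
analysed by declaring predictor and target sets explicitly (fit any
variables as a panel), but the engine does not attempt time-lagged
orientation on its own.

### Interpretive choices

The influence statistic, hidden-layer size, resample count and split
fractions are interpretive defaults, exposed in [annConfig()] and
documented as replaceable: other weight-composition rules (e.g.
Garson-style absolute shares) could be substituted without touching the
rest of the pipeline. BMI and endotoxin can be appended to the panel as
pseudo-genes (`includeCovariates`), treated identically to genes.

### Numerical choices

* Weight initialisation: uniform on $(-0.5, 0.5)$, per-resample seed
  derived deterministically from the configuration seed and the target's
  panel index, so a full run is reproducible from `(data, seed)` alone.
* Learning rate 0.2 with momentum 0.9 and up to 1000 epochs: on
  unit-interval-scaled data this reaches test $R^2 \ge 0.99$ (median over
  resamples) on noiseless linear targets — the learnability contract the
  test suite enforces.
* Early stopping restores the best-validation weights
  (patience 30 epochs), which is what bounds over-fitting under the
  Monte Carlo loop.
* Zero-variance predictors are dropped with a warning rather than
  failing the run.

### Calibration against a permutation null

On a panel of mutually independent genes the inferred $|W|$ should not
systematically exceed a null built by destroying association:
[interactionNullQuantile()] permutes each gene's sample vector
independently (marginals preserved, associations destroyed — permuting
whole samples would preserve the joint distribution and destroy nothing),
re-runs the full inference, and pools null $|W|$ entries across
permutations. The acceptance suite checks that at most 10% of real
entries exceed the pooled 95th percentile (10 permutations; fewer make
the exceedance fraction too noisy an estimator to be meaningful).

## The statistical workflow around the engine

**Normality routing.** Every univariate comparison is routed by the
D'Agostino–Pearson omnibus test: a vector is parametric iff the omnibus
$p \ge 0.05$ *and* both the transformed skewness-z and kurtosis-z lie in
$(-1.96, 1.96)$. The skewness (D'Agostino 1970) and kurtosis
(Anscombe–Glynn 1983) transforms are implemented in the package and
verified to 1e-9 against an independent reference implementation on
frozen vectors. Vectors with $n < 8$ or zero variance are routed
non-parametric with a warning, never an error. For group designs the
routing is assessed on the pooled within-group residuals; for paired
designs on the differences (the design leaves this open; residuals are
the vector whose normality the parametric test actually assumes).

**Group comparisons.** Parametric: one-way ANOVA + Tukey HSD.
Non-parametric: Kruskal–Wallis + Dunn's rank-based post hoc with tie
correction; Dunn's unadjusted p-values are reported alongside
Bonferroni-adjusted ones, since the adjustment convention is a reporting
choice. Paired: two-tailed paired t-test or Wilcoxon signed-rank; all-zero
differences return $p = 1$ by convention. Factorial treatment designs:
two-way ANOVA with type-II sums of squares (robust default when cell
sizes differ mildly; identical to the classical decomposition on balanced
data, which is what the brute-force oracle tests use) followed by Tukey
across cell means; empty cells are rejected. Significance is fixed at
0.05 throughout.

**Correlations.** Pearson only, with per-variable log routing: a
variable routed non-parametric is natural-log-transformed before the
correlation, provided it is strictly positive (rejected by name
otherwise). Routing is per variable, not pairwise, so a gene's transform
does not depend on which partner it is correlated against. Delta
correlations (post − pre per subject) disable log routing entirely —
changes may be negative. Missing data are handled pairwise-complete, so
the effective $n$ is an output of each cell, and the matrix export
carries r, p, n and the star convention (\*, \*\*, \*\*\*, \*\*\*\* at
0.05/0.01/0.001/0.0001). No multiplicity correction is applied across
matrix cells; cells are reported as computed.

**qPCR quantification.** Duplicate Ct values are collapsed by mean, with
a flag (never a drop) when the replicate range exceeds 0.5 Ct. Relative
expression is $2^{-\Delta Ct}$ against the housekeeping gene — perfect
efficiency, single reference; efficiency correction and multi-reference
normalisation are out of scope. [foldChange()] supplies the calibrator
step when a control group is the reference.

**Clinical indices.** HOMA-IR $=$ glucose (mmol/L) $\times$ insulin
(mIU/L) $/\,22.5$; insulin conversion 6.945 pmol/L per mIU/L (standard
clinical constant; both unit read-outs are exposed since assays report
either); Friedewald LDL $=$ TC $-$ HDL $-$ TG$/2.2$ with the usual
validity bound TG $\le 4.5$ mmol/L (the source formula states no bound;
this is the accepted one); %EWL $=$ (pre $-$ post)$/$(pre $-$ ideal)
$\times 100$, requiring positive excess weight.

## The synthetic cohort generator

The generator is first-class, tested code: it defines the study
conditions every downstream stage is validated against.

**Model.** A latent multivariate Gaussian over all variables (genes and
covariates) with a user-specified target correlation matrix. Transcripts
are exponentiated — lognormal, strictly positive, right-skewed like qPCR
fold-changes — with group mean shifts applied on the latent (log) scale.
Covariates are mapped linearly onto their natural scales using per-group
means and SDs; the defaults follow the cohort characteristics of the
emulated design (three BMI strata of n = 44/49/63, a paired subcohort of
n = 26, glucose/insulin/lipid/BMI group means and spreads from the study
population; serum endotoxin, not tabulated there, is set to a realistic
gradient of 4.0/5.5/7.0 EU/mL rising with BMI and 8.5 pre-surgery).
Concentrations are floored at zero, which censors a small fraction of
draws for covariates whose mean sits within ~1.5 SD of zero (insulin:
~9%); the induced correlation attenuation stays within the ±0.05
consistency budget at n = 5000.

**Correlation targets are latent-scale.** Because expression is
exponentiated, the Pearson correlation of *natural-scale* expression is
attenuated by a known factor (~0.94 at the default latent SD of 0.5);
consistency checks therefore compare empirical correlations of
log-expression (and natural-scale covariates) against the targets — the
same scale the analysis layer's log routing recovers on skewed data.
User targets that are mildly inconsistent (not jointly realisable) are
repaired by eigenvalue clipping and re-normalisation
([repairCorrelation()]); anything with an eigenvalue below −1e-6 is
rejected, naming the eigenvalue. The *repaired* matrix is what the
[PlantedTruth-class] records.

**Planted networks.** A signed adjacency over the genes is superimposed
as a linear structural model on the latent gene block,
$x = (I - A^\top)^{-1}\varepsilon$: with a zero adjacency the correlation
targets hold exactly; with planted edges, children depend linearly on
parents on the latent scale. This is the ground truth the ANNi recovery
tests score against (AUROC of $|W|$, planted pairs among the top ranked
pairs, sign fidelity).

**Paired designs.** Pre-surgery draws use the `pre` group column; the
per-subject change vector is multivariate normal with mean
`surgeryEffect` and the shared correlation targets on the delta scale, and
`post = pre + delta` on the *measurement* scale — so a planted
delta-coupling (e.g. −0.5 between the change in endotoxin and the change
in CIDEA) is exactly the Pearson correlation [deltaCorrelation()]
measures. Post-surgery expression is floored at 1% of the pre value; with
the default effect sizes the floor binds rarely and biases the null-case
delta means by well under the 2-SEM test band.

**Ct plates.** `Ct_gene − Ct_L19 = −log2(expression)` plus replicate
noise (default 0.15 Ct, two replicates, housekeeping baseline 18
cycles). With zero noise, quantification inverts the simulation exactly
(to double-precision rounding), which is the round-trip contract the
acceptance suite asserts at 1e-12.

**What the generator does not emulate.** Assay plate layouts, depot
pairs from the same subject (depot is an optional label only),
amplification-efficiency variation, batch effects, drop-out or detection
limits, and heavy-tailed measurement error. Passing recovery tests on
this generator therefore demonstrates correctness of the pipeline's
computations under its stated model, not robustness of ANNi to real-data
pathologies.

## Problem sizes used by the test and acceptance suites

Chosen as the smallest sizes at which each property is a sharp check:
generator consistency at n = 5000 (max entrywise error ≤ 0.05); type-I
calibration with 1000 null replicates per design (0.05 ± 3 binomial SE);
ANNi recovery on 15 genes / 5 planted strong edges / n = 150 / 50
resamples (AUROC ≥ 0.8, ≥ 4 of 5 planted pairs in the top 5); null
calibration on 12 independent genes with 10 permutations; end-to-end
determinism on a 36-sample demo cohort run twice.

## Reproducibility

Every stochastic stage takes an explicit integer seed; sub-seeds are
derived deterministically (per target gene, per resample, per
permutation), so equal `(data, config, seed)` reproduce results
bit-for-bit — including the pipeline outputs, whose manifest records MD5
checksums and deliberately carries no timestamps.

## A small worked run

```{r example, eval = FALSE}
cfg <- syntheticConfig(seed = 1)
se <- generateCohort(cfg)         # 156 samples, 13 genes
res <- compareGroups(expressionTable(se)[, "CIDEA"],
                     clinicalTable(se)$group)
branch(res); pValue(res)

im <- interactionMatrix(se[1:6, ], annConfig(mcResamples = 10L, seed = 1))
collapseInfluence(im)
exportNetwork(rankInteractions(im, 10), "network.sif", "sif")
```

## Known limitations

* Edge orientation is not identifiable from cross-sectional data; report
  pair-level findings.
* The influence statistic is one defensible reading of "signal directions
  and prediction weights"; it is configurable but not validated against
  alternatives here.
* Dunn's post hoc is reported both unadjusted and Bonferroni-adjusted;
  users must choose one convention before looking at results.
* The two-group path (t-test / Mann–Whitney) is deliberately not part of
  [compareGroups()], which targets the three-stratum design; use the base
  tests directly for two groups.
* No efficiency-corrected qPCR models, no mixed-effects or
  repeated-measures models beyond the paired tests, and no multiple-testing
  correction across correlation matrices.
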