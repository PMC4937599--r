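---
title: "Scoring parainflammation in tumor transcriptomes: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring parainflammation in tumor transcriptomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(parainflam)
```

## The problem

Parainflammation (PI) is a low-grade, cell-autonomous inflammatory
transcriptional state, intermediate between tissue homeostasis and overt
chronic inflammation. It is defined here operationally, by a gene
signature: inflammatory-response genes upregulated in epithelial cells of
mouse gut models that develop the state, without the immune-cell
infiltrate of classic inflammation. The analytic difficulty in bulk human
tumor data is exactly that infiltrate: inflammatory transcripts in a bulk
profile may come from the tumor cells themselves (the phenomenon of
interest) or from infiltrating leukocytes (a confounder). The package
implements the full chain from signature derivation to infiltration
adjustment, per-sample scoring, threshold calibration, and the downstream
clinical associations, together with a synthetic-cohort simulator that
encodes the statistical structure every stage assumes, so each stage has
a parameter-recovery test.

## Signature derivation

The inflammatory universe is built by list voting
(`assemble_inflammatory_genes()`): a gene belongs to the universe when it
appears in at least `min_votes = 2` of the curated inflammatory /
innate-immunity lists supplied. Symbol comparison is case-insensitive
(mouse `Ifitm3` and human `IFITM3` conventions both occur in curated
lists); the first-seen casing is preserved.

Differential expression (`differential_expression()`) wraps DESeq2 —
median-of-ratios size factors, trended dispersion shrinkage, Wald test —
with two deliberate settings: `independentFiltering = FALSE` and
`cooksCutoff = FALSE`, so every tested gene receives a plain
Benjamini-Hochberg adjusted p-value and results are deterministic. No
fold-change shrinkage is applied because the downstream selection
thresholds operate on the raw fold ratio: `select_up()` keeps genes with
fold ratio strictly greater than 2 and adjusted p strictly below 0.01
(both configurable); `select_down()` mirrors it below 1/2. Strictness at
the boundary matters: a gene at exactly twofold is excluded.

The signature (`derive_signature()`) is the intersection of the two
model contrasts' up-lists with the inflammatory universe, computed after
case normalization and invariant to input order. The same construction
applied to the down-lists yields the down-signature (`derive_down()`).
`expand_signature()` grows the gene set by per-gene Spearman correlation
with the PI score (cutoff 0.5, strict); Spearman is the default because
every score correlation in the pipeline is rank-based, but the method is
configurable. A constant gene has undefined correlation, treated as 0,
hence excluded.

## Infiltration adjustment

The per-sample immune-infiltration estimate is the log2 expression of a
single pan-hematopoietic marker, CD45 (*PTPRC*). On reference normal
tissue, `fit_infiltration_slopes()` fits, per gene and per tissue, an
ordinary least-squares line of the gene's log2 expression on CD45 log2
expression; at least 20 samples per tissue are required (tissues below
that are skipped with a warning), zero-variance genes get slope 0, and
negative slopes are kept as fitted. `adjust_expression()` then removes
`slope * CD45` from each tumor sample of the matching tissue — only the
slope term; intercepts are stored for diagnostics but never applied,
since subtracting a per-gene constant cannot change any between-sample
comparison the pipeline makes. Finally each gene is shifted so its
minimum over the adjusted cohort is exactly 0. The shift is computed
within the cohort being adjusted, not the training normals, so adjusted
values are always non-negative on the data at hand. The reference gene
itself is excluded from slope adjustment (its self-slope of 1 would
cancel it identically) but is min-shifted like every other row.

Whether values should additionally be floored before the min-shift is
left open by the procedure's description; since the min-shift makes the
output non-negative either way and only within-gene spacing could
differ, the package applies no extra floor.

## PI scoring and the PI+ threshold

`ssgsea_score()` implements the single-sample enrichment statistic:
genes ranked by decreasing expression, ties broken by lexical gene-symbol
order so scores are fully deterministic; walking down the ranking, the
score integrates the difference between the weighted in-set ECDF (weights
`rank^alpha`, rank `n` at the top, normalized over in-set genes) and the
uniform out-of-set ECDF. `alpha = 0.25` is the default weighting;
`alpha = 1` gives fully rank-weighted scoring and `alpha = 0` uniform
weights. The statistic is rank-based, hence invariant to any strictly
monotone per-sample transform of expression.

Two numerical properties deserve note. First, under random placement of
the gene set the score has mean exactly 0 only for uniform weights
(`alpha = 0`); for `alpha > 0` the weighted in-set ECDF rises faster than
the uniform out-of-set ECDF in expectation and the null mean is positive.
This bias is harmless here because thresholds are calibrated on the same
statistic, so it cancels in classification — but raw scores should never
be interpreted as centered at zero. Second, scores of two disjoint gene
sets computed on the same sample compete for ranks: activating one
program pushes the other set's genes down the ranking. In small gene
universes (hundreds of genes) this rank competition visibly
anti-correlates otherwise independent set scores; on genome-scale
platforms (tens of thousands of genes) it is negligible. The package's
construction tests therefore use universes of 2000+ genes when asserting
correlation recovery.

`score_cohort()` scores every sample over the signature genes present in
the matrix, refuses when fewer than half the signature is available
(configurable floor), and by default divides all raw scores by their
cohort range. Range normalization yields sub-unit scores of the kind the
method's printed thresholds have, but — like any ssGSEA score — they
remain comparable only within one platform and gene universe. The score
table and threshold objects both record the universe size, and
`classify_samples()` refuses to combine scores and thresholds from
different universes.

`calibrate_threshold()` takes adjacent-normal scores — non-tumor tissue
from cancer patients, the natural null for "no tumor PI program" — and
returns the empirical `1 - 0.05` quantile under the type-7
linear-interpolation convention (scores 1..100 at 5% give exactly 95.05).
Ties can leave slightly more than the target fraction strictly above an
interpolated quantile, so the threshold steps up to the next observed
value until at most 5% of calibration scores strictly exceed it; on
continuous scores this is a no-op. Classification is strict: a sample
exactly at the threshold is PI−. Shifted scores (`raw − threshold`) make
PI+ samples positive by construction. Calibration pools adjacent normals
across types by default; per-type calibration is a matter of subsetting
the input table.

## Overexpression statistics for cell-line panels

Cell-line panels have no adjacent normals, so tumor-intrinsic activation
shows up instead as bimodality: a background mode plus an overexpressing
subpopulation. `find_expression_peak()` estimates the mode by Gaussian
kernel density with Silverman's rule-of-thumb bandwidth on a fixed
512-point grid spanning the data range (grid argmax, ties to the smallest
location; at least 20 values required; a constant vector returns the
constant). KDE was chosen over histogram binning to make the mode
estimator continuous and directly testable; the fixed grid makes it
deterministic. `overexpression_counts()` counts samples strictly above
`peak + delta` with `delta = 1` log2 (twofold over the peak), and
`compare_gene_pools()` compares the proportion of genes over a 10%
overexpression rate (2×2 chi-square without continuity correction) and
the median overexpressing-sample counts (two-sided rank-sum) between the
signature and reference pools, with seeded subsampling when pool sizes
are matched.

## Association stages

* `correlate_with_genesets()` scores any named gene sets with the same
  ssGSEA engine and reports Spearman correlations with the PI score,
  optionally stratified by cancer type.
* `cytolytic_activity()` is the geometric mean of GZMA and PRF1
  linear-scale expression, the standard anti-tumor cytolysis metric.
* `p53_association()` reports the rank-sum test of scores by mutation
  status, PI+ proportions by status with a chi-square test, and — across
  three or more cancer types — the Spearman correlation of per-type
  mutation rate with per-type PI+ rate.
* `cox_survival()` fits a Cox proportional-hazards model (Efron tie
  handling, the default approximation when event times tie; the choice
  is inconsequential for continuous times) of survival on the PI score,
  optionally controlling for age, smoking or p53 status; at least 10
  events are required and convergence warnings are surfaced in the
  result.
* `km_logrank()` computes Kaplan-Meier curves per PI call, a two-sided
  log-rank test, and the PI−/PI+ ratio of median survival times, reported
  only when both medians are reached.
* `nsaid_response_test()` is the treatment-response statistic: a
  two-sided rank-sum comparison of the signature genes' treated-versus-
  control log2 fold changes against all other genes', plus the fraction
  of signature genes that went down. When every fold change is identical
  the normal approximation degenerates (0/0); the package defines p = 1
  for that case.

All tests are two-sided and invariant to sample order.

## The synthetic-cohort simulator

The simulator is the package's test surface: it generates cohorts with
exactly the structure the pipeline assumes, plus the ground truth needed
to check recovery. One `sim_config()` object carries every parameter;
each generator call seeds its own RNG sub-stream from `seed` (restoring
the caller's RNG state), so a fixed seed gives byte-identical output and
the gene universe — names, baselines, CD45 slopes — is shared across
generators for a given seed, which is what lets a model trained on
simulated reference normals adjust a simulated tumor cohort.

The defaults encode the study conditions the pipeline targets:

* `pi_positive_fraction = 0.259` — the pan-cancer PI+ proportion.
* Activated genes per PI+ sample ~ Binomial(40, 17/40): a median of 17
  of the 40 signature genes active, reproducing the observation that
  different PI+ samples activate different signature subsets.
* `p53_intercept = qlogis(0.152)`, `p53_coef = qlogis(0.354) −
  qlogis(0.152)`: mutation probability 15.2% in PI− and 35.4% in PI+
  samples on the logit scale.
* Quantities with no reported value are fixed once at realistic levels
  for log2 bulk expression data: residual noise sd 0.5 log2; activation
  effect per sample ~ N(2, 0.5) log2 (truncated at 0); CD45 log2
  expression ~ N(5, 1) (truncated at 0); half of (gene, tissue) pairs
  CD45-independent and the rest with slopes ~ N(0.5, 0.3); NB dispersion
  0.1 for counts; cell-line bimodality with weight 0.2, separation
  3 log2, component sd 0.3; exponential survival with baseline hazard
  1e-3 per day, log-hazard coefficient 0.8 per unit latent PI intensity,
  and independent uniform censoring calibrated to a 30% censor rate.
  The within-cohort variance of activation strength is deliberately a
  free parameter (`activation_sd`); no reported value constrains it.

The latent PI intensity of a PI+ sample is `effect × n_activated / 40`,
i.e., the average log2 elevation over the signature; it drives the
survival hazard and is recorded in the truth object, so hazard-coefficient
recovery can be tested against the exact generating covariate.

What the simulator does **not** emulate — and what passing tests
therefore do not establish about real data: gene-level marginal
distributions of real platforms, batch effects, isoform structure,
gene-gene correlation beyond the CD45 slopes and the PI program, or
tissue-specific PI prevalence (the PI+ fraction is constant across
simulated tissues). Recovery results here validate the implementation,
not the biology.

## Problem sizes used in the checks

The shipped checks run the full chain — reference normals, slope
fitting, adjustment, scoring, calibration, classification, p53 and
survival associations — at 5000 genes × 2000 samples, and verify it
completes within 10 minutes on a single CPU (it takes well under one).
Statistical recovery checks use sizes chosen for estimator precision:
slope recovery at 200 normals per tissue (max error < 0.1 at noise sd
0.3), Cox recovery as the mean of 10 cohorts of 2000 tumors (within
±0.15 of the true 0.8), threshold calibration on 1000 normals, PI+
fraction recovery on 1000 tumors with 800 calibration normals (within
±5 points of an embedded 25%), and a single ~1000-gene null count
simulation for DE type-I control.

## Known limitations

* The exact normalization that produced the method's published numeric
  thresholds (0.2951 on tumor data, 0.1859 on cell lines) cannot be
  pinned down from the method description; range normalization gives
  scores of the same sub-unit character, but absolute threshold values
  are platform-specific and should always be recalibrated on adjacent
  normals from the platform at hand.
* The mode estimator's bandwidth choice (Silverman) is a documented
  decision, not a reproduction of the original peak detection, whose
  binning/smoothing is unspecified; peak locations on real panels may
  differ slightly.
* Whether the published per-model inflammatory up-counts were computed
  before or after restricting to the inflammatory universe is ambiguous;
  the package intersects after selection, and the choice is exposed by
  construction (selection and intersection are separate operations).
* The DE engine matches DESeq2 defaults minus independent filtering and
  outlier replacement; small gene-count differences against other
  settings of the same engine are expected.
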