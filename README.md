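# parainflam

Parainflammation (PI) is a low-grade, cell-autonomous inflammatory
transcriptional state, intermediate between tissue homeostasis and
chronic inflammation, that tumors can express without any immune-cell
infiltrate. `parainflam` is an R package for detecting and quantifying
this state in bulk tumor and cell-line transcriptomes: it derives a PI
gene signature from differential expression of inflammatory-response
genes, removes the immune-infiltration confound from bulk profiles,
scores each sample, calls PI+ tumors against a threshold calibrated on
adjacent normal tissue, and runs the downstream clinical associations
(p53-mutation enrichment, survival, NSAID response). It is aimed at
computational biologists working with expression matrices of the
TCGA/GTEx/CCLE kind.

## The method

**Signature.** An inflammatory-response gene universe is assembled by
voting across curated lists (a gene qualifies when it appears in ≥ 2 of
them). Genes upregulated (fold ratio > 2, BH-adjusted p < 0.01; DESeq2
Wald test) in *both* of two mouse gut models of the state, intersected
with the universe, form the up-signature; the mirrored construction gives
the down-signature.

**Infiltration adjustment.** For gene *g*, tissue *t* and sample *s*
with CD45 (*PTPRC*) log2 expression *c_s*, reference normal tissue gives
an OLS slope *β_{g,t}* of expression on CD45, and tumor expression is
adjusted as

    x'_{g,s} = x_{g,s} − β_{g,t(s)} · c_s,

then each gene is shifted so its cohort minimum is 0. This removes the
component of inflammatory expression attributable to infiltrating
leukocytes rather than the tumor cells.

**PI score and PI+ call.** The per-sample score is a single-sample gene
set enrichment (ssGSEA) statistic: with genes ranked by decreasing
expression, the score integrates the difference between the
rank-weighted in-set ECDF (weights rank^α, α = 0.25) and the uniform
out-of-set ECDF. The PI+ threshold is the score that only 5% of adjacent
normal samples exceed (type-7 empirical quantile); a tumor strictly above
it is PI+.

**Cell-line overexpression.** Panels without adjacent normals are
assessed by distribution-peak statistics: a gene's mode is located by
Gaussian KDE (Silverman bandwidth, 512-point grid) and samples more than
twofold (1 log2) above the mode are counted as overexpressing; signature
and reference gene pools are compared by chi-square and rank-sum tests.

**Associations.** Spearman correlations of the PI score with other
gene-set scores (same engine), the GZMA/PRF1 cytolytic metric, rank-sum
and chi-square tests against p53 status, Cox proportional hazards and
Kaplan-Meier/log-rank survival analysis, and a rank-sum NSAID-response
test on treated-vs-control fold changes.

A synthetic-cohort simulator (`sim_config()`, `simulate_*()`) generates
reference normals, tumor cohorts, cell-line panels and count experiments
with known ground truth, so every stage has a parameter-recovery test.

## Worked example

End-to-end on a simulated pan-cancer cohort (3 tissues, 300 tumors, 120
adjacent normals, 2000 genes, 25.9% of tumors carrying the PI program):

```r
library(parainflam)

cfg     <- sim_config(seed = 42)
normals <- simulate_reference_normals(cfg)
model   <- fit_infiltration_slopes(normals$expression, normals$annotations)

cohort   <- simulate_tumor_cohort(cfg)
adjusted <- adjust_expression(cohort$expression, model, cohort$annotations)
scores   <- score_cohort(adjusted, cohort$truth$signature)

ann <- cohort$annotations
normal_scores <- scores[scores$sample_id %in%
                          ann$sample_id[ann$class == "normal"], ]
threshold <- calibrate_threshold(normal_scores)
#> <pi_threshold> 0.3132329 ( 5 % of 120 calibration normals above )

tumor_scores <- scores[scores$sample_id %in%
                         ann$sample_id[ann$class == "tumor"], ]
calls <- classify_samples(tumor_scores, threshold)
head(calls[, c("sample_id", "raw_score", "shifted_score", "call")], 4)
#>           sample_id raw_score shifted_score call
#> 1 tissue01_tumor001 0.2090613   -0.10417160  PI-
#> 2 tissue01_tumor002 0.2223759   -0.09085700  PI-
#> 3 tissue01_tumor003 0.6392941    0.32606124  PI+
#> 4 tissue01_tumor004 0.2686221   -0.04461074  PI-

mean(calls$call == "PI+")          # 0.317; simulated truth is 0.270
```

The raw score is the range-normalized ssGSEA enrichment; the shifted
score subtracts the calibrated threshold, so PI+ samples are exactly
those with positive shifted scores. The called fraction (31.7%) sits
above the true 27.0% because, by calibration, ~5% of PI− tumors also
exceed the threshold.

Clinical associations on the same cohort:

```r
tum <- ann[match(calls$sample_id, ann$sample_id), ]
tum$score <- calls$raw_score
tum$call  <- calls$call

cox_survival(tum, "score")
#> Cox log hazard ratio per unit PI score: 1.32 (p = 8.7e-06)
km_logrank(tum, "call")
#> log-rank p = 5.3e-05; median survival ratio PI-/PI+ = 1.77
p53_association(calls$raw_score, tum$p53_status, calls = calls$call)
#> PI+ rate: 42.6% in p53-mutant vs 29.3% in WT (chi-square p = 0.057)
```

Higher PI scores carry a higher mortality hazard, PI− patients reach
their median survival 1.77× later than PI+ patients, and PI+ calls are
enriched in p53-mutant samples — the direction the cohort was simulated
with (the simulator links mutation probability to PI status on the logit
scale).

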