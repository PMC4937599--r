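Package: parainflam
Title: Parainflammation Signature Scoring and Association Analysis for
    Tumor Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Derives a parainflammation (PI) gene signature from
    differential expression of inflammatory-response genes, adjusts bulk
    tumor expression for immune infiltration using CD45 (PTPRC) slopes
    learned from reference normal tissue, computes per-sample ssGSEA PI
    scores, calibrates a PI-positive threshold on adjacent-normal
    samples, quantifies per-gene overexpression rates via
    density-peak detection in cell-line panels, and runs the downstream
    association stages (gene-set correlations, p53-mutation enrichment,
    survival, NSAID response). Includes a synthetic-cohort simulator
    with known ground truth for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    stats,
    utils,
    jsonlite,
    survival,
    DESeq2
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
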