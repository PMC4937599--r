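#' Two-group differential expression on RNA-seq counts
#'
#' Wald-test differential expression of `condition` against `reference`
#' using DESeq2 (median-of-ratios size factors, trended dispersion
#' shrinkage, Wald test on the log2 fold change) with plain
#' Benjamini-Hochberg adjustment over all tested genes
#' (`independentFiltering = FALSE`, `cooksCutoff = FALSE`, so results are
#' deterministic and every tested gene gets an adjusted p). Genes with
#' all-zero counts across the two groups are excluded from testing. No
#' fold-change shrinkage is applied: the downstream signature thresholds
#' operate on the raw fold ratio.
#'
#' @param counts integer matrix, genes x samples (non-negative).
#' @param conditions data.frame with `sample_id` and `condition` columns,
#'   or a vector of condition labels aligned with `colnames(counts)`.
#' @param condition,reference labels of the test and reference groups;
#'   each needs >= 2 replicates.
#' @return data.frame with columns `gene`, `base_mean`, `log2_fold`,
#'   `p`, `adj_p`, one row per tested gene.
#' @export
differential_expression <- function(counts, conditions, condition,
                                    reference) {
  if (is.data.frame(conditions)) {
    stopifnot(all(c("sample_id", "condition") %in% names(conditions)))
    cond <- setNames(as.character(conditions$condition),
                     conditions$sample_id)[colnames(counts)]
  } else {
    cond <- setNames(as.character(conditions), colnames(counts))
  }
  if (anyNA(cond)) {
    stop("differential_expression: samples missing condition labels",
         call. = FALSE)
  }
  if (any(counts < 0)) {
    stop("differential_expression: negative counts", call. = FALSE)
  }
  if (any(counts != round(counts))) {
    stop("differential_expression: counts must be integers", call. = FALSE)
  }
  sel <- cond %in% c(condition, reference)
  if (sum(cond == condition) < 2 || sum(cond == reference) < 2) {
    stop("differential_expression: >= 2 replicates per group required ",
         "(no dispersion estimate otherwise)", call. = FALSE)
  }
  sub <- counts[, sel, drop = FALSE]
  keep <- rowSums(sub) > 0
  sub <- sub[keep, , drop = FALSE]
  storage.mode(sub) <- "integer"

  coldata <- data.frame(
    condition = factor(cond[sel], levels = c(reference, condition)))
  dds <- DESeq2::DESeqDataSetFromMatrix(sub, coldata, ~condition)
  dds <- DESeq2::DESeq(dds, quiet = TRUE)
  res <- DESeq2::results(dds,
                         contrast = c("condition", condition, reference),
                         independentFiltering = FALSE,
                         cooksCutoff = FALSE)
  out <- data.frame(gene = rownames(res),
                    base_mean = res$baseMean,
                    log2_fold = res$log2FoldChange,
                    p = res$pvalue,
                    adj_p = res$padj,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Select up- / downregulated genes from a DE result
#'
#' `select_up()` keeps genes with fold ratio strictly greater than
#' `min_fold` and adjusted p strictly below `max_adj_p`;
#' `select_down()` is the mirror image (fold ratio strictly below
#' `1 / min_fold`). A gene at exactly the fold threshold is excluded.
#'
#' @param de data.frame from [differential_expression()].
#' @param min_fold fold-ratio threshold (linear scale, default 2).
#' @param max_adj_p adjusted-p threshold (default 0.01).
#' @return a `gene_list` of selected genes (input order preserved).
#' @export
select_up <- function(de, min_fold = 2, max_adj_p = 0.01) {
  stopifnot(min_fold > 0, max_adj_p > 0)
  keep <- !is.na(de$adj_p) & 2^de$log2_fold > min_fold &
    de$adj_p < max_adj_p
  gene_list("upregulated", de$gene[keep],
            source = sprintf("fold > %g & adj_p < %g", min_fold, max_adj_p))
}

#' @rdname select_up
#' @export
select_down <- function(de, min_fold = 2, max_adj_p = 0.01) {
  stopifnot(min_fold > 0, max_adj_p > 0)
  keep <- !is.na(de$adj_p) & 2^de$log2_fold < 1 / min_fold &
    de$adj_p < max_adj_p
  gene_list("downregulated", de$gene[keep],
            source = sprintf("fold < 1/%g & adj_p < %g", min_fold,
                             max_adj_p))
}
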