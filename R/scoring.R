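# Single-sample gene set enrichment (ssGSEA) PI scoring, threshold
# calibration on adjacent normals, and PI+/PI- classification.

#' ssGSEA enrichment score for one sample
#'
#' Genes are ranked by decreasing expression (ties broken by stable
#' lexical gene-symbol order, so scores are deterministic). Walking down
#' the ranked list, the score accumulates the difference between the
#' weighted in-set ECDF — weights are `rank^alpha`, with rank `n` for the
#' most highly expressed gene, normalized over in-set genes — and the
#' uniform out-of-set ECDF, summed over all positions (integrated
#' difference). The score is rank-based: any strictly monotone transform
#' of the expression vector leaves it unchanged.
#'
#' @param expr named numeric vector of log2 expression over the gene
#'   universe (one sample).
#' @param signature character vector of signature genes; at least one must
#'   be present and the signature must be smaller than the universe.
#' @param alpha rank-weight exponent (default 0.25; `alpha = 1` gives
#'   fully rank-weighted scoring).
#' @return a single numeric enrichment score.
#' @export
ssgsea_score <- function(expr, signature, alpha = 0.25) {
  if (is.null(names(expr))) {
    stop("ssgsea_score: expression vector must be named by gene",
         call. = FALSE)
  }
  n <- length(expr)
  in_set <- names(expr) %in% signature
  n_in <- sum(in_set)
  if (n_in == 0) {
    stop("ssgsea_score: no signature gene present in the sample",
         call. = FALSE)
  }
  if (n_in >= n) {
    stop("ssgsea_score: signature must be smaller than the gene universe",
         call. = FALSE)
  }
  if (all(expr == expr[1])) {
    stop("ssgsea_score: all-constant expression vector", call. = FALSE)
  }
  ord <- order(-expr, names(expr), method = "radix")
  in_ord <- in_set[ord]
  w <- (n:1)^alpha
  ecdf_in <- cumsum(ifelse(in_ord, w, 0)) / sum(w[in_ord])
  ecdf_out <- cumsum(!in_ord) / (n - n_in)
  sum(ecdf_in - ecdf_out)
}

#' Score every sample of a cohort with ssGSEA
#'
#' Applies [ssgsea_score()] column-wise over the signature genes present
#' in the matrix. Missing signature genes are reported; if fewer than
#' `min_present` of the signature is available the call refuses. With
#' `normalize = "range"` (the default) all raw scores are divided by
#' `max - min` over the cohort, giving sub-unit scores comparable within
#' (and only within) the cohort's platform.
#'
#' @param expr log2 expression matrix, genes x samples.
#' @param signature character vector (or `pi_signature`, whose `up` set is
#'   used).
#' @param alpha rank-weight exponent, see [ssgsea_score()].
#' @param normalize "range" or "none".
#' @param min_present minimum fraction of the signature that must be
#'   present (default 0.5).
#' @return a `pi_score_table` data.frame (`sample_id`, `raw_score`,
#'   `n_genes_used`) with attributes `universe_size`, `signature_size` and
#'   `normalize`.
#' @export
score_cohort <- function(expr, signature, alpha = 0.25,
                         normalize = c("range", "none"),
                         min_present = 0.5) {
  normalize <- match.arg(normalize)
  if (inherits(signature, "pi_signature")) signature <- signature$up
  signature <- unique(as.character(signature))
  if (length(signature) == 0) {
    stop("score_cohort: empty signature", call. = FALSE)
  }
  present <- intersect(signature, rownames(expr))
  if (length(present) < min_present * length(signature)) {
    stop("score_cohort: only ", length(present), " of ",
         length(signature), " signature genes present (< ",
         round(100 * min_present), "% floor)", call. = FALSE)
  }
  missing <- setdiff(signature, present)
  if (length(missing)) {
    message("score_cohort: ", length(missing),
            " signature gene(s) not in matrix: ",
            paste(missing, collapse = ", "))
  }
  raw <- apply(expr, 2, ssgsea_score, signature = present, alpha = alpha)
  if (normalize == "range") {
    rng <- max(raw) - min(raw)
    if (rng > 0) raw <- raw / rng
  }
  out <- data.frame(sample_id = colnames(expr),
                    raw_score = unname(raw),
                    n_genes_used = length(present),
                    stringsAsFactors = FALSE)
  attr(out, "universe_size") <- nrow(expr)
  attr(out, "signature_size") <- length(signature)
  attr(out, "normalize") <- normalize
  class(out) <- c("pi_score_table", "data.frame")
  out
}

#' Score a cohort with the downregulated PI gene set
#'
#' Identical mechanics to [score_cohort()] applied to the down set of the
#' signature; errors on an empty down set.
#'
#' @param expr log2 expression matrix.
#' @param down_signature character vector or `pi_signature` (whose `down`
#'   set is used).
#' @param ... passed to [score_cohort()].
#' @export
down_score <- function(expr, down_signature, ...) {
  genes <- if (inherits(down_signature, "pi_signature")) {
    down_signature$down
  } else {
    as.character(down_signature)
  }
  if (length(genes) == 0) {
    stop("down_score: empty down-signature", call. = FALSE)
  }
  score_cohort(expr, genes, ...)
}

#' Calibrate the PI+ threshold on adjacent-normal scores
#'
#' The threshold is the empirical `1 - calibration_fraction` quantile of
#' the adjacent-normal scores (type-7 linear-interpolation quantile, the
#' convention under which scores 1..100 at 5% give 95.05), so at most a
#' `calibration_fraction` of calibration samples lie strictly above it.
#' `calibration_fraction = 0` returns the maximum score.
#'
#' @param normal_scores numeric vector of adjacent-normal scores, or a
#'   `pi_score_table` (its `raw_score` column is used).
#' @param calibration_fraction target exceedance fraction (default 0.05,
#'   i.e., only 5% of adjacent normals above the threshold).
#' @param min_n minimum calibration samples (default 20).
#' @return a `pi_threshold`: list with `threshold`,
#'   `calibration_fraction`, `n_calibration` and `universe_size` (NA when
#'   calibrated from a bare vector). The universe size guards against
#'   classifying scores computed on a different gene universe, which are
#'   not comparable.
#' @export
calibrate_threshold <- function(normal_scores, calibration_fraction = 0.05,
                                min_n = 20) {
  universe <- NA_integer_
  if (is.data.frame(normal_scores)) {
    universe <- attr(normal_scores, "universe_size") %||% NA_integer_
    normal_scores <- normal_scores$raw_score
  }
  normal_scores <- normal_scores[is.finite(normal_scores)]
  if (length(normal_scores) == 0) {
    stop("calibrate_threshold: empty calibration set", call. = FALSE)
  }
  if (length(normal_scores) < min_n) {
    stop("calibrate_threshold: need >= ", min_n, " calibration scores, got ",
         length(normal_scores), call. = FALSE)
  }
  stopifnot(calibration_fraction >= 0, calibration_fraction <= 1)
  thr <- unname(quantile(normal_scores, 1 - calibration_fraction,
                         type = 7))
  # ties can leave slightly more than the target fraction strictly above;
  # step the threshold up to the next observed value until the guarantee
  # holds (no-op in the continuous case)
  while (mean(normal_scores > thr) > calibration_fraction) {
    thr <- min(normal_scores[normal_scores > thr])
  }
  structure(list(threshold = thr,
                 calibration_fraction = calibration_fraction,
                 n_calibration = length(normal_scores),
                 universe_size = universe),
            class = "pi_threshold")
}

#' @export
print.pi_threshold <- function(x, ...) {
  cat("<pi_threshold>", format(x$threshold), "(",
      100 * x$calibration_fraction, "% of", x$n_calibration,
      "calibration normals above )\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Classify samples as PI+ / PI-
#'
#' A sample is PI+ iff its raw score is strictly over the threshold; the
#' shifted score is `raw - threshold`, so PI+ samples have positive
#' shifted scores. When both the score table and the threshold record a
#' gene-universe size the two must match: ssGSEA scores from different
#' platforms / universes are not comparable and classification refuses.
#'
#' @param scores a `pi_score_table` from [score_cohort()].
#' @param threshold a `pi_threshold` from [calibrate_threshold()], or a
#'   bare number.
#' @return the score table with `shifted_score`, `call` ("PI+" / "PI-")
#'   and `threshold` columns added.
#' @export
classify_samples <- function(scores, threshold) {
  thr_universe <- NA_integer_
  if (inherits(threshold, "pi_threshold")) {
    thr_universe <- threshold$universe_size
    threshold <- threshold$threshold
  }
  stopifnot(is.numeric(threshold), length(threshold) == 1,
            is.finite(threshold))
  score_universe <- attr(scores, "universe_size") %||% NA_integer_
  if (!is.na(thr_universe) && !is.na(score_universe) &&
      thr_universe != score_universe) {
    stop("classify_samples: threshold calibrated on a ", thr_universe,
         "-gene universe but scores use ", score_universe,
         " genes; ssGSEA scores are not comparable across universes",
         call. = FALSE)
  }
  scores$shifted_score <- scores$raw_score - threshold
  scores$call <- ifelse(scores$raw_score > threshold, "PI+", "PI-")
  scores$threshold <- threshold
  scores
}
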