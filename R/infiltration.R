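# Immune-infiltration adjustment. The per-sample infiltration estimate is
# the log2 expression of a single pan-hematopoietic marker (PTPRC / CD45).
# Reference normals provide, per tissue and gene, the normal linear
# association of expression with CD45; subtracting slope * CD45 from tumor
# expression removes the component explained by infiltrating leukocytes.

#' Fit per-gene, per-tissue infiltration slopes on reference normals
#'
#' Ordinary least squares of each gene's log2 expression on the reference
#' gene's log2 expression, independently within each tissue. Genes with
#' zero variance get slope 0; tissues with fewer than `min_train` samples
#' are skipped with a warning. The reference gene regressed on itself has
#' slope 1 by construction.
#'
#' @param normals log2 expression matrix of reference normal samples,
#'   genes x samples.
#' @param annotations data.frame with `sample_id` and `tissue` columns.
#' @param reference_gene infiltration marker row (default "PTPRC").
#' @param min_train minimum samples per tissue (default 20).
#' @return an `infiltration_model`: reference gene, slope and intercept
#'   matrices (genes x tissues; intercepts are stored for diagnostics but
#'   never applied), and per-tissue training counts.
#' @export
fit_infiltration_slopes <- function(normals, annotations,
                                    reference_gene = "PTPRC",
                                    min_train = 20) {
  if (!reference_gene %in% rownames(normals)) {
    stop("fit_infiltration_slopes: reference gene `", reference_gene,
         "` not in matrix", call. = FALSE)
  }
  stopifnot(all(c("sample_id", "tissue") %in% names(annotations)))
  tissue <- setNames(as.character(annotations$tissue),
                     annotations$sample_id)[colnames(normals)]
  if (anyNA(tissue)) {
    stop("fit_infiltration_slopes: samples missing tissue annotation",
         call. = FALSE)
  }
  tissues <- unique(tissue)
  slopes <- intercepts <- matrix(
    NA_real_, nrow = nrow(normals), ncol = 0,
    dimnames = list(rownames(normals), NULL))
  n_train <- integer(0)
  for (t in tissues) {
    cols <- which(tissue == t)
    if (length(cols) < min_train) {
      warning("fit_infiltration_slopes: tissue `", t, "` has only ",
              length(cols), " samples (< ", min_train, "); skipped")
      next
    }
    x <- normals[, cols, drop = FALSE]
    cd45 <- x[reference_gene, ]
    cc <- cd45 - mean(cd45)
    denom <- sum(cc^2)
    if (denom == 0) {
      b <- rep(0, nrow(x))
    } else {
      b <- as.vector(x %*% cc) / denom
    }
    # zero-variance genes carry no signal: slope 0
    b[apply(x, 1, function(v) all(v == v[1]))] <- 0
    a <- rowMeans(x) - b * mean(cd45)
    slopes <- cbind(slopes, b)
    intercepts <- cbind(intercepts, a)
    colnames(slopes)[ncol(slopes)] <- t
    colnames(intercepts)[ncol(intercepts)] <- t
    n_train[t] <- length(cols)
  }
  if (ncol(slopes) == 0) {
    stop("fit_infiltration_slopes: no tissue had >= ", min_train,
         " samples", call. = FALSE)
  }
  structure(list(reference_gene = reference_gene,
                 slopes = slopes,
                 intercepts = intercepts,
                 n_train = n_train),
            class = "infiltration_model")
}

#' @export
print.infiltration_model <- function(x, ...) {
  cat("<infiltration_model> reference:", x$reference_gene, "\n")
  cat("  tissues:", paste(colnames(x$slopes), collapse = ", "), "\n")
  cat("  genes:", nrow(x$slopes), "; trained on",
      paste(x$n_train, collapse = "/"), "samples\n")
  invisible(x)
}

#' Adjust a cohort's expression for immune infiltration
#'
#' Subtracts, per gene and sample,
#' `slope[gene, tissue(sample)] * cd45[sample]` (only the slope is
#' applied; intercepts are ignored), then shifts each gene so its minimum
#' over the cohort is exactly 0. The reference gene itself is not
#' slope-adjusted (it would cancel identically) but is min-shifted like
#' every other gene. Genes absent from the model are shift-only.
#'
#' @param cohort log2 expression matrix, genes x samples.
#' @param model an `infiltration_model`.
#' @param annotations data.frame with `sample_id` and `tissue`.
#' @param on_missing what to do with samples whose tissue is absent from
#'   the model: "error" (default) or "passthrough" (shift-only).
#' @return adjusted matrix (same dimensions) with attributes `shift`
#'   (per-gene shift applied) and `reference_gene`.
#' @export
adjust_expression <- function(cohort, model, annotations,
                              on_missing = c("error", "passthrough")) {
  on_missing <- match.arg(on_missing)
  stopifnot(inherits(model, "infiltration_model"))
  ref <- model$reference_gene
  if (!ref %in% rownames(cohort)) {
    stop("adjust_expression: reference gene `", ref,
         "` not in cohort; refusing to substitute a proxy", call. = FALSE)
  }
  stopifnot(all(c("sample_id", "tissue") %in% names(annotations)))
  tissue <- setNames(as.character(annotations$tissue),
                     annotations$sample_id)[colnames(cohort)]
  if (anyNA(tissue)) {
    stop("adjust_expression: samples missing tissue annotation",
         call. = FALSE)
  }
  missing_t <- setdiff(unique(tissue), colnames(model$slopes))
  if (length(missing_t) && on_missing == "error") {
    stop("adjust_expression: tissue(s) not in model: ",
         paste(missing_t, collapse = ", "),
         " (use on_missing = \"passthrough\" to shift-only)",
         call. = FALSE)
  }
  cd45 <- cohort[ref, ]
  shared <- intersect(rownames(cohort), rownames(model$slopes))
  shared <- setdiff(shared, ref)
  out <- cohort
  for (t in intersect(unique(tissue), colnames(model$slopes))) {
    cols <- which(tissue == t)
    out[shared, cols] <- cohort[shared, cols, drop = FALSE] -
      model$slopes[shared, t] %o% cd45[cols]
  }
  shift <- apply(out, 1, min)
  out <- out - shift
  attr(out, "shift") <- shift
  attr(out, "reference_gene") <- ref
  out
}
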