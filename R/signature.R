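#' Parainflammation gene signature
#'
#' Holds the up- and downregulated PI gene sets (disjoint by
#' construction), an optional correlation-expanded set, the species of the
#' symbols and free-form provenance.
#'
#' @param up,down character vectors of gene symbols; must be disjoint
#'   (case-insensitive).
#' @param species "mouse" or "human".
#' @param expanded optional data.frame (`gene`, `corr`) from
#'   [expand_signature()].
#' @param provenance free-form list.
#' @return a `pi_signature` object.
#' @export
pi_signature <- function(up, down = character(0), species = "human",
                         expanded = NULL, provenance = list()) {
  up <- unique(as.character(up))
  down <- unique(as.character(down))
  if (length(intersect(toupper(up), toupper(down)))) {
    stop("pi_signature: up and down sets overlap", call. = FALSE)
  }
  species <- match.arg(species, c("human", "mouse"))
  structure(list(up = up, down = down, species = species,
                 expanded = expanded, provenance = provenance),
            class = "pi_signature")
}

#' @export
print.pi_signature <- function(x, ...) {
  cat("<pi_signature> species:", x$species, "\n")
  cat("  up:", length(x$up), "genes; down:", length(x$down), "genes\n")
  if (!is.null(x$expanded)) {
    cat("  expanded:", nrow(x$expanded), "correlated genes\n")
  }
  invisible(x)
}

#' Derive the PI signature by intersecting model up-lists with the
#' inflammatory universe
#'
#' The signature is the set of genes upregulated in *both* model contrasts
#' that also belong to the inflammatory-response universe. Comparison is
#' case-insensitive and invariant to input order; the casing of the
#' inflammatory universe is kept. `derive_down()` applies the same
#' intersection to downregulated lists.
#'
#' @param up_model1,up_model2 gene lists upregulated in the two models.
#' @param inflammatory the inflammatory universe [gene_list()]
#'   (non-empty).
#' @return a `gene_list`, sorted.
#' @export
derive_signature <- function(up_model1, up_model2, inflammatory) {
  if (length(inflammatory) == 0) {
    stop("derive_signature: empty inflammatory universe", call. = FALSE)
  }
  shared <- intersect(toupper(as.character(up_model1)),
                      toupper(as.character(up_model2)))
  infl <- as.character(inflammatory)
  out <- sort(infl[toupper(infl) %in% shared])
  gene_list("pi_signature_up", out,
            source = "intersect(model1 up, model2 up, inflammatory)")
}

#' @rdname derive_signature
#' @param down_model1,down_model2 gene lists downregulated in the two
#'   models.
#' @export
derive_down <- function(down_model1, down_model2, inflammatory) {
  out <- derive_signature(down_model1, down_model2, inflammatory)
  attr(out, "name") <- "pi_signature_down"
  out
}

#' Expand the signature by correlation with the PI score
#'
#' Finds genes whose expression across samples correlates with the
#' per-sample PI score above `min_corr` (strict). Genes with zero variance
#' have undefined correlation, treated as 0 and therefore excluded.
#'
#' @param expr log2 expression matrix, genes x samples.
#' @param scores a `pi_score_table` (or numeric vector named by sample)
#'   computed on the same samples.
#' @param min_corr correlation cutoff (default 0.5).
#' @param method correlation method (default "spearman").
#' @return data.frame (`gene`, `corr`) sorted by decreasing correlation.
#' @export
expand_signature <- function(expr, scores, min_corr = 0.5,
                             method = c("spearman", "pearson")) {
  method <- match.arg(method)
  s <- if (is.data.frame(scores)) {
    setNames(scores$raw_score, scores$sample_id)
  } else {
    scores
  }
  common <- intersect(colnames(expr), names(s))
  if (length(common) < 3) {
    stop("expand_signature: need >= 3 samples with scores", call. = FALSE)
  }
  x <- expr[, common, drop = FALSE]
  s <- s[common]
  rho <- apply(x, 1, function(v) {
    if (sd(v) == 0) return(0)
    cor(v, s, method = method)
  })
  rho[is.na(rho)] <- 0
  keep <- rho > min_corr
  out <- data.frame(gene = rownames(x)[keep], corr = unname(rho[keep]),
                    stringsAsFactors = FALSE)
  out[order(-out$corr, out$gene), , drop = FALSE]
}
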