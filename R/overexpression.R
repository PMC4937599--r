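# Distribution-peak "overexpression rate" statistic for cell-line panels:
# find the mode of each gene's log2 expression distribution by kernel
# density, call a sample overexpressing when it exceeds the mode by more
# than `delta` log2 units (twofold for delta = 1), and compare gene pools
# on the resulting per-gene rates.

#' Locate the peak (mode) of a log2 expression distribution
#'
#' Gaussian kernel density with Silverman's rule-of-thumb bandwidth,
#' evaluated on a fixed 512-point grid spanning the data range; the peak
#' is the grid argmax (ties resolve to the smallest location). A
#' zero-variance vector returns the constant value.
#'
#' @param values numeric vector of log2 expression (>= `min_n` finite
#'   values).
#' @param min_n minimum number of values (default 20).
#' @return peak location (numeric scalar).
#' @export
find_expression_peak <- function(values, min_n = 20) {
  values <- values[is.finite(values)]
  if (length(values) < min_n) {
    stop("find_expression_peak: need >= ", min_n, " finite values, got ",
         length(values), call. = FALSE)
  }
  if (all(values == values[1])) {
    return(values[1])
  }
  d <- density(values, bw = "nrd0", n = 512, from = min(values),
               to = max(values))
  d$x[which.max(d$y)]
}

#' Per-gene overexpression counts over the distribution peak
#'
#' For each gene, finds the expression peak across the panel and counts
#' samples whose expression strictly exceeds `peak + delta` (`delta = 1`
#' log2 = twofold over the peak). Genes missing from the matrix are
#' reported and skipped.
#'
#' @param expr log2 expression matrix, genes x samples.
#' @param genes character vector (or `gene_list`) of genes to assess.
#' @param delta log2 margin over the peak (default 1).
#' @param min_n passed to [find_expression_peak()].
#' @return a `peak_stats` data.frame (`gene`, `peak`, `cutoff`, `n_over`,
#'   `frac_over`) with attribute `n_samples`.
#' @export
overexpression_counts <- function(expr, genes, delta = 1, min_n = 20) {
  genes <- as.character(genes)
  missing <- setdiff(genes, rownames(expr))
  if (length(missing)) {
    message("overexpression_counts: skipping ", length(missing),
            " gene(s) not in matrix: ", paste(missing, collapse = ", "))
  }
  genes <- intersect(genes, rownames(expr))
  if (length(genes) == 0) {
    stop("overexpression_counts: no requested gene present", call. = FALSE)
  }
  n <- ncol(expr)
  peak <- vapply(genes, function(g) {
    find_expression_peak(expr[g, ], min_n = min_n)
  }, numeric(1))
  cutoff <- peak + delta
  n_over <- vapply(genes, function(g) sum(expr[g, ] > cutoff[g]),
                   integer(1))
  out <- data.frame(gene = genes, peak = unname(peak),
                    cutoff = unname(cutoff), n_over = unname(n_over),
                    frac_over = unname(n_over) / n,
                    stringsAsFactors = FALSE)
  attr(out, "n_samples") <- n
  class(out) <- c("peak_stats", "data.frame")
  out
}

#' Cumulative overexpression-rate curve
#'
#' The fraction of genes whose overexpression rate is at least `x`, for
#' every rate value observed (plus 0): a non-increasing step curve with
#' value 1 at `x = 0`.
#'
#' @param stats a `peak_stats` data.frame from [overexpression_counts()].
#' @return data.frame (`rate`, `fraction_of_genes`).
#' @export
cumulative_overexpression_curve <- function(stats) {
  if (nrow(stats) == 0) {
    stop("cumulative_overexpression_curve: empty stats", call. = FALSE)
  }
  rates <- sort(unique(c(0, stats$frac_over)))
  data.frame(rate = rates,
             fraction_of_genes = vapply(rates, function(x) {
               mean(stats$frac_over >= x)
             }, numeric(1)))
}

#' Compare a target gene pool's overexpression against reference pools
#'
#' For the target set and each reference pool: the proportion of genes
#' overexpressed in at least `rate_cut` of samples (compared by a 2x2
#' chi-square test without continuity correction) and the median number of
#' overexpressing samples (compared by a two-sided rank-sum test). Pools
#' can optionally be subsampled (seeded, without replacement) to the
#' target size.
#'
#' @param target `peak_stats` for the signature genes.
#' @param pools named list of `peak_stats` for the comparison pools (e.g.,
#'   all genes, random inflammatory genes).
#' @param rate_cut overexpression-rate cut (default 0.10, i.e., 10% of
#'   samples).
#' @param match_size subsample each pool to `nrow(target)` genes?
#' @param seed seed for the subsampling (required when `match_size`).
#' @return data.frame, one row per pool: proportions over `rate_cut`,
#'   chi-square p, medians of `n_over`, rank-sum p.
#' @export
compare_gene_pools <- function(target, pools, rate_cut = 0.10,
                               match_size = FALSE, seed = NULL) {
  stopifnot(is.list(pools), length(pools) >= 1)
  if (is.null(names(pools)) || any(!nzchar(names(pools)))) {
    stop("compare_gene_pools: pools must be named", call. = FALSE)
  }
  if (any(vapply(pools, nrow, integer(1)) == 0)) {
    stop("compare_gene_pools: empty pool", call. = FALSE)
  }
  rows <- lapply(names(pools), function(nm) {
    pool <- pools[[nm]]
    if (match_size && nrow(pool) > nrow(target)) {
      if (is.null(seed)) {
        stop("compare_gene_pools: `seed` required when match_size = TRUE",
             call. = FALSE)
      }
      pool <- with_sim_seed(seed, 0,
                            pool[sample(nrow(pool), nrow(target)), ])
    }
    t_hit <- sum(target$frac_over >= rate_cut)
    p_hit <- sum(pool$frac_over >= rate_cut)
    tab <- rbind(c(t_hit, nrow(target) - t_hit),
                 c(p_hit, nrow(pool) - p_hit))
    chisq_p <- suppressWarnings(
      chisq.test(tab, correct = FALSE)$p.value)
    rs_p <- ranksum_p(target$n_over, pool$n_over)
    data.frame(pool = nm,
               target_prop = t_hit / nrow(target),
               pool_prop = p_hit / nrow(pool),
               chisq_p = chisq_p,
               target_median = median(target$n_over),
               pool_median = median(pool$n_over),
               ranksum_p = rs_p,
               n_target = nrow(target),
               n_pool = nrow(pool),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Two-sided Wilcoxon rank-sum p with a defined value (1) in the fully
# tied / zero-rank-variance case, where the normal approximation is 0/0.
ranksum_p <- function(x, y) {
  if (length(unique(c(x, y))) == 1) {
    return(1)
  }
  p <- suppressWarnings(wilcox.test(x, y)$p.value)
  if (is.nan(p)) 1 else p
}
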