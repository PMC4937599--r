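# Downstream association stages: PI-score correlations with other
# gene-set scores, the cytolytic-activity metric, p53-mutation enrichment,
# survival (Cox and Kaplan-Meier / log-rank), and the NSAID-response rank
# test. Standard tests go through stats:: and survival::; effect sizes and
# grouping conventions are fixed here.

#' Correlate PI scores with other gene-set enrichment scores
#'
#' Scores each gene set with the same ssGSEA engine used for the PI score
#' and reports its Spearman correlation with the PI score, optionally
#' stratified by a grouping factor (e.g., cancer type). Gene sets entirely
#' absent from the matrix give NA with a warning.
#'
#' @param pi_scores `pi_score_table` or named numeric vector of PI scores.
#' @param expr log2 expression matrix the scores were computed on.
#' @param genesets named list of character vectors.
#' @param by optional named factor/character vector (per sample) to
#'   stratify by; NULL pools all samples.
#' @param method correlation method (default "spearman").
#' @param ... passed to [score_cohort()].
#' @return data.frame (`geneset`, `group`, `rho`, `n`).
#' @export
correlate_with_genesets <- function(pi_scores, expr, genesets, by = NULL,
                                    method = "spearman", ...) {
  stopifnot(is.list(genesets), !is.null(names(genesets)))
  s <- if (is.data.frame(pi_scores)) {
    setNames(pi_scores$raw_score, pi_scores$sample_id)
  } else {
    pi_scores
  }
  common <- intersect(colnames(expr), names(s))
  if (length(common) < 3) {
    stop("correlate_with_genesets: need >= 3 scored samples",
         call. = FALSE)
  }
  groups <- if (is.null(by)) {
    list(all = common)
  } else {
    split(common, as.character(by[common]))
  }
  rows <- list()
  for (nm in names(genesets)) {
    gs <- intersect(as.character(genesets[[nm]]), rownames(expr))
    if (length(gs) == 0) {
      warning("correlate_with_genesets: gene set `", nm,
              "` absent from matrix; rho = NA")
      for (g in names(groups)) {
        rows[[paste(nm, g)]] <- data.frame(
          geneset = nm, group = g, rho = NA_real_,
          n = length(groups[[g]]), stringsAsFactors = FALSE)
      }
      next
    }
    gs_scores <- score_cohort(expr[, common, drop = FALSE], gs,
                              min_present = 0, ...)
    gv <- setNames(gs_scores$raw_score, gs_scores$sample_id)
    for (g in names(groups)) {
      ids <- groups[[g]]
      rows[[paste(nm, g)]] <- data.frame(
        geneset = nm, group = g,
        rho = cor(s[ids], gv[ids], method = method),
        n = length(ids), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out
}

#' Immune cytolytic activity metric
#'
#' Geometric mean of the linear-scale expression of GZMA and PRF1,
#' `sqrt((GZMA + pseudo) * (PRF1 + pseudo))`. Log2 input is exponentiated
#' first.
#'
#' @param expr expression matrix containing GZMA and PRF1 rows.
#' @param scale "log2" (default; values are exponentiated) or "linear".
#' @param pseudo pseudo-count added on the linear scale (default 0).
#' @return named numeric vector, one value per sample.
#' @export
cytolytic_activity <- function(expr, scale = c("log2", "linear"),
                               pseudo = 0) {
  scale <- match.arg(scale)
  need <- c("GZMA", "PRF1")
  if (!all(need %in% rownames(expr))) {
    stop("cytolytic_activity: missing ",
         paste(setdiff(need, rownames(expr)), collapse = " and "),
         call. = FALSE)
  }
  a <- expr["GZMA", ]
  b <- expr["PRF1", ]
  if (scale == "log2") {
    a <- 2^a
    b <- 2^b
  }
  sqrt((a + pseudo) * (b + pseudo))
}

#' Association of PI with p53 mutation status
#'
#' Three views of the association: (i) a two-sided rank-sum test of PI
#' scores in p53-mutant versus wild-type samples; (ii) PI+ proportions per
#' p53 status with a 2x2 chi-square test (no continuity correction); and,
#' when a per-sample grouping is supplied, (iii) the Spearman correlation
#' across groups (cancer types) of the p53-mutation rate with the PI+
#' rate.
#'
#' @param scores numeric vector of PI scores, or a classified
#'   `pi_score_table` (raw scores and calls are taken from it).
#' @param p53_status per-sample status, "mut" / "WT" (aligned with
#'   `scores`); both levels must be represented.
#' @param calls optional per-sample "PI+" / "PI-" calls (not needed when
#'   `scores` is a classified table).
#' @param by optional per-sample group labels for the per-type rate
#'   correlation.
#' @return list with `score_test`, `proportion_test` and (when `by` is
#'   given) `rate_correlation`, each carrying effect, p and n.
#' @export
p53_association <- function(scores, p53_status, calls = NULL, by = NULL) {
  if (is.data.frame(scores)) {
    if (is.null(calls) && "call" %in% names(scores)) calls <- scores$call
    scores <- scores$raw_score
  }
  p53_status <- as.character(p53_status)
  n_mut <- sum(p53_status == "mut", na.rm = TRUE)
  n_wt <- sum(p53_status == "WT", na.rm = TRUE)
  if (n_mut == 0 || n_wt == 0) {
    stop("p53_association: both p53 statuses must be represented",
         call. = FALSE)
  }
  mut <- p53_status == "mut"
  score_test <- list(
    statistic = "rank-sum (PI score, mut vs WT)",
    effect = median(scores[mut], na.rm = TRUE) -
      median(scores[!mut & p53_status == "WT"], na.rm = TRUE),
    p = ranksum_p(scores[mut & !is.na(scores)],
                  scores[p53_status == "WT" & !is.na(scores)]),
    n = c(mut = n_mut, WT = n_wt))

  proportion_test <- NULL
  if (!is.null(calls)) {
    pi_pos <- calls == "PI+"
    tab <- table(factor(p53_status, levels = c("mut", "WT")),
                 factor(pi_pos, levels = c(TRUE, FALSE)))
    prop <- prop.table(tab, 1)[, 1]
    proportion_test <- list(
      statistic = "chi-square (PI+ proportion, mut vs WT)",
      effect = unname(prop["mut"] - prop["WT"]),
      proportions = prop,
      p = suppressWarnings(chisq.test(tab, correct = FALSE)$p.value),
      n = c(mut = n_mut, WT = n_wt))
  }

  rate_correlation <- NULL
  if (!is.null(by) && !is.null(calls)) {
    by <- as.character(by)
    d <- data.frame(by = by, mut = mut, pi = calls == "PI+")
    d <- d[!is.na(d$by) & !is.na(d$mut) & !is.na(d$pi), ]
    rates <- do.call(rbind, lapply(split(d, d$by), function(g) {
      data.frame(mut_rate = mean(g$mut), pi_rate = mean(g$pi))
    }))
    if (nrow(rates) < 3) {
      warning("p53_association: < 3 groups; per-type rate correlation ",
              "omitted")
    } else {
      ct <- suppressWarnings(
        cor.test(rates$mut_rate, rates$pi_rate, method = "spearman"))
      rate_correlation <- list(
        statistic = "Spearman (per-type p53 rate vs PI+ rate)",
        effect = unname(ct$estimate),
        p = ct$p.value,
        n = nrow(rates))
    }
  }

  out <- list(score_test = score_test, proportion_test = proportion_test,
              rate_correlation = rate_correlation)
  out[!vapply(out, is.null, logical(1))]
}

#' Cox proportional-hazards association of survival with the PI score
#'
#' Maximizes the Cox partial likelihood (Efron approximation for tied
#' event times) of survival on `covariate`, optionally controlling for
#' additional covariates (e.g., age, smoking, p53 status). At least 10
#' events are required. Complete separation / non-convergence is flagged
#' in the result.
#'
#' @param records data.frame with `time` (> 0), `event` (1 death /
#'   0 censored) and the covariate columns.
#' @param covariate name of the score column.
#' @param controls character vector of additional covariate columns.
#' @return list: `log_hr` (per unit covariate), `se`, `p` (Wald, two
#'   sided), `n`, `n_events`, `flagged` (convergence warning) and the
#'   fitted model.
#' @export
cox_survival <- function(records, covariate, controls = character(0)) {
  stopifnot(all(c("time", "event", covariate, controls) %in%
                  names(records)))
  d <- records[stats::complete.cases(
    records[, c("time", "event", covariate, controls)]), ]
  if (any(d$time <= 0)) {
    stop("cox_survival: non-positive survival times", call. = FALSE)
  }
  if (sum(d$event) == 0) {
    stop("cox_survival: no events", call. = FALSE)
  }
  if (sum(d$event) < 10) {
    stop("cox_survival: < 10 events; refusing to fit", call. = FALSE)
  }
  if (var(d[[covariate]]) == 0) {
    return(list(log_hr = 0, se = NA_real_, p = NA_real_, n = nrow(d),
                n_events = sum(d$event), flagged = "constant covariate",
                model = NULL))
  }
  rhs <- paste(c(covariate, controls), collapse = " + ")
  f <- as.formula(paste("survival::Surv(time, event) ~", rhs))
  flagged <- NULL
  fit <- withCallingHandlers(
    survival::coxph(f, data = d, ties = "efron"),
    warning = function(w) {
      flagged <<- conditionMessage(w)
      invokeRestart("muffleWarning")
    })
  s <- summary(fit)
  list(log_hr = unname(coef(fit)[covariate]),
       se = unname(s$coefficients[covariate, "se(coef)"]),
       p = unname(s$coefficients[covariate, "Pr(>|z|)"]),
       n = nrow(d),
       n_events = sum(d$event),
       flagged = flagged,
       model = fit)
}

#' Kaplan-Meier curves and log-rank test between PI+ and PI- samples
#'
#' Kaplan-Meier product-limit estimates per group, a two-sided log-rank
#' test, and the ratio of median survival times when both medians are
#' reached (otherwise NA). Groups are ordered by byte order of their
#' labels (locale-independent), which puts "PI+" before "PI-"; the ratio
#' is second group over first, i.e., PI- over PI+ for PI calls, so a
#' value above 1 means PI+ patients die earlier.
#'
#' @param records data.frame with `time`, `event` and the grouping column.
#' @param group name of the grouping column (e.g., the PI call).
#' @return list: `p` (log-rank), `medians` (named per group),
#'   `median_ratio`, `curves` (data.frame of per-group KM coordinates:
#'   time, surv, n_risk), `n` per group.
#' @export
km_logrank <- function(records, group = "call") {
  stopifnot(all(c("time", "event", group) %in% names(records)))
  d <- records[stats::complete.cases(records[, c("time", "event", group)]), ]
  # byte-order levels: locale-independent, and puts "PI+" before "PI-"
  # so the median ratio is PI- over PI+
  lev <- sort(unique(as.character(d[[group]])), method = "radix")
  if (length(lev) < 2) {
    stop("km_logrank: need two non-empty groups", call. = FALSE)
  }
  d$.group <- factor(as.character(d[[group]]), levels = lev)
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ .group, data = d)
  p <- 1 - pchisq(sd_$chisq, df = length(sd_$n) - 1)
  fit <- survival::survfit(survival::Surv(time, event) ~ .group, data = d)
  tab <- summary(fit)$table
  medians <- setNames(tab[, "median"],
                      sub("^\\.group=", "", rownames(tab)))
  ratio <- if (length(medians) == 2 && !anyNA(medians)) {
    unname(medians[2] / medians[1])
  } else {
    NA_real_
  }
  strata <- rep(sub("^\\.group=", "", names(fit$strata)), fit$strata)
  curves <- data.frame(group = strata, time = fit$time, surv = fit$surv,
                       n_risk = fit$n.risk, stringsAsFactors = FALSE)
  list(p = p, medians = medians, median_ratio = ratio, curves = curves,
       n = setNames(as.vector(table(d$.group)), levels(d$.group)))
}

#' NSAID-response rank test on treated-vs-control fold changes
#'
#' Two-sided rank-sum test comparing the signature genes' log2 fold
#' changes (treated vs control) against all other genes', plus the
#' fraction of signature genes with negative fold change. Requires fold
#' changes for at least half the signature.
#'
#' @param logfc named numeric vector of per-gene log2 fold changes.
#' @param signature character vector (or `pi_signature`, whose `up` set is
#'   used).
#' @param min_coverage minimum fraction of the signature that must be
#'   covered (default 0.5).
#' @return list: `p` (rank-sum), `median_shift` (signature median minus
#'   background median), `frac_down`, `n_signature`, `n_background`.
#' @export
nsaid_response_test <- function(logfc, signature, min_coverage = 0.5) {
  if (inherits(signature, "pi_signature")) signature <- signature$up
  signature <- unique(as.character(signature))
  if (is.null(names(logfc))) {
    stop("nsaid_response_test: `logfc` must be named by gene",
         call. = FALSE)
  }
  in_sig <- names(logfc) %in% signature
  if (sum(in_sig) < min_coverage * length(signature)) {
    stop("nsaid_response_test: fold changes cover only ", sum(in_sig),
         " of ", length(signature), " signature genes (< ",
         round(100 * min_coverage), "%)", call. = FALSE)
  }
  if (sum(!in_sig) == 0) {
    stop("nsaid_response_test: empty background", call. = FALSE)
  }
  sig_fc <- logfc[in_sig]
  bg_fc <- logfc[!in_sig]
  list(p = ranksum_p(sig_fc, bg_fc),
       median_shift = median(sig_fc) - median(bg_fc),
       frac_down = mean(sig_fc < 0),
       n_signature = sum(in_sig),
       n_background = sum(!in_sig))
}
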