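# Downstream association statistics: gene-set correlations, cytolytic
# metric, p53 enrichment, survival, NSAID response.

test_that("PI score correlates ~1 with itself and ~0 with independent
           random gene sets", {
  # slopes off so the two gene sets are independent by construction
  # (with CD45 slopes on, infiltration drives both scores); a large gene
  # universe keeps the rank competition induced by PI activation small
  cfg <- small_config(n_genes = 2000, slope_zero_fraction = 1, seed = 71)
  sim <- simulate_tumor_cohort(cfg)
  tum <- sim$annotations$sample_id[sim$annotations$class == "tumor"]
  expr <- sim$expression[, tum]
  scores <- score_cohort(expr, sim$truth$signature)
  sets <- list(self = sim$truth$signature,
               random = sprintf("BG%05d", 201:240),
               absent = c("NOPE1", "NOPE2"))
  expect_warning(res <- correlate_with_genesets(scores, expr, sets),
                 "absent")
  expect_gt(res$rho[res$geneset == "self"], 0.99)
  expect_lt(abs(res$rho[res$geneset == "random"]), 0.35)
  expect_true(is.na(res$rho[res$geneset == "absent"]))
})

test_that("a co-activated gene program is recovered with high rho", {
  # cell-line-like setting (no infiltration slopes) and a 2000-gene
  # universe so ssGSEA rank competition between the disjoint sets stays
  # small relative to the shared program
  cfg <- sim_config(n_genes = 2000, n_tissues = 2,
                    n_reference_per_tissue = 50,
                    n_tumors_per_tissue = 200, n_normals_per_tissue = 30,
                    slope_zero_fraction = 1, seed = 72)
  sim <- simulate_tumor_cohort(cfg)
  tum <- names(sim$truth$latent)
  expr <- sim$expression[, tum]
  # couple 30 background genes to the PI program at activation strength
  coupled <- sprintf("BG%05d", 1:30)
  pi_on <- sim$truth$pi_status[tum]
  expr[coupled, pi_on] <- expr[coupled, pi_on] + cfg$activation_mean
  scores <- score_cohort(expr, sim$truth$signature)
  res <- correlate_with_genesets(scores, expr, list(coupled = coupled))
  expect_gt(res$rho[res$geneset == "coupled"], 0.5)
})

test_that("cytolytic activity is the geometric mean of GZMA and PRF1", {
  expr <- rbind(GZMA = log2(c(4, 9, 1)),
                PRF1 = log2(c(16, 4, 1)),
                OTHER = c(1, 1, 1))
  colnames(expr) <- c("s1", "s2", "s3")
  expect_equal(unname(cytolytic_activity(expr)),
               c(sqrt(4 * 16), sqrt(9 * 4), 1))
  # GZMA = PRF1 = c on the linear scale gives c
  lin <- rbind(GZMA = c(3, 0), PRF1 = c(3, 5))
  colnames(lin) <- c("a", "b")
  out <- cytolytic_activity(lin, scale = "linear")
  expect_equal(unname(out), c(3, 0))
  expect_equal(unname(cytolytic_activity(lin, scale = "linear",
                                         pseudo = 1)),
               c(sqrt(4 * 4), sqrt(1 * 6)))
  expect_error(cytolytic_activity(expr[-1, , drop = FALSE]), "GZMA")
})

test_that("p53 association recovers the embedded positive link", {
  cfg <- survival_config(2000, seed = 73)
  sim <- simulate_tumor_cohort(cfg)
  ann <- sim$annotations[sim$annotations$class == "tumor", ]
  pi_true <- sim$truth$pi_status[ann$sample_id]
  set.seed(73)
  scores <- sim$truth$latent[ann$sample_id] +
    rnorm(nrow(ann), 0, 0.05)  # latent plus noise stands in for scores
  calls <- ifelse(pi_true, "PI+", "PI-")
  expect_warning(
    res <- p53_association(scores, ann$p53_status, calls = calls,
                           by = ann$tissue),
    "< 3 groups")  # single simulated tissue: rate correlation omitted
  expect_lt(res$score_test$p, 0.01)
  expect_gt(res$score_test$effect, 0)
  expect_gt(res$proportion_test$proportions["mut"],
            res$proportion_test$proportions["WT"])
  expect_lt(res$proportion_test$p, 0.01)
  expect_error(p53_association(scores, rep("mut", length(scores))),
               "both p53 statuses")
})

test_that("per-type p53 rates track PI+ rates across cancer types", {
  # 12 types with PI+ rates spanning 0-70%; mutation probability rises
  # with PI status, so types with more PI+ samples mutate more often
  set.seed(75)
  types <- sprintf("type%02d", 1:12)
  pi_rate <- seq(0, 0.7, length.out = 12)
  rows <- lapply(seq_along(types), function(i) {
    n <- 300
    pi <- runif(n) < pi_rate[i]
    mut <- runif(n) < plogis(qlogis(0.152) +
                               (qlogis(0.354) - qlogis(0.152)) * pi)
    data.frame(type = types[i], pi = pi, mut = mut)
  })
  d <- do.call(rbind, rows)
  res <- p53_association(scores = rnorm(nrow(d)),
                         p53_status = ifelse(d$mut, "mut", "WT"),
                         calls = ifelse(d$pi, "PI+", "PI-"),
                         by = d$type)
  expect_gt(res$rate_correlation$effect, 0.5)
  expect_lt(res$rate_correlation$p, 0.05)
  expect_identical(res$rate_correlation$n, 12L)
})

test_that("p53 association is null when status is shuffled", {
  set.seed(74)
  scores <- rnorm(400)
  status <- sample(c("mut", "WT"), 400, replace = TRUE)
  calls <- sample(c("PI+", "PI-"), 400, replace = TRUE)
  res <- p53_association(scores, status, calls = calls)
  expect_gt(res$score_test$p, 0.001)
  expect_lt(abs(res$proportion_test$effect), 0.15)
})

test_that("rank-sum p matches exact enumeration on tiny groups", {
  # enumeration oracle: exact two-sided p over all C(8,4) labelings
  x <- c(1.2, 3.4, 2.2, 5.6)
  y <- c(0.3, 0.9, 4.1, 1.1)
  pooled <- c(x, y)
  r <- rank(pooled)
  w_obs <- sum(r[1:4])
  combs <- combn(8, 4)
  w_all <- apply(combs, 2, function(i) sum(r[i]))
  mu <- mean(w_all)
  p_exact <- mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-12)
  res <- nsaid_response_test(setNames(pooled, paste0("g", 1:8)),
                             paste0("g", 1:4), min_coverage = 1)
  expect_equal(res$p, p_exact, tolerance = 1e-12)
})

test_that("Cox recovers the simulated hazard coefficient within 0.15", {
  ests <- vapply(1:10, function(i) {
    cfg <- sim_config(n_genes = 50, n_tissues = 1,
                      n_reference_per_tissue = 20,
                      n_tumors_per_tissue = 2000,
                      n_normals_per_tissue = 1,
                      hazard_coef = 0.8, seed = 300 + i)
    sim <- simulate_tumor_cohort(cfg)
    ann <- sim$annotations[sim$annotations$class == "tumor", ]
    ann$latent <- sim$truth$latent[ann$sample_id]
    cox_survival(ann, "latent")$log_hr
  }, numeric(1))
  expect_lt(abs(mean(ests) - 0.8), 0.15)
})

test_that("Cox handles degenerate covariates and validates input", {
  cfg <- survival_config(300, seed = 76)
  sim <- simulate_tumor_cohort(cfg)
  ann <- sim$annotations[sim$annotations$class == "tumor", ]
  ann$flat <- 1
  res <- cox_survival(ann, "flat")
  expect_identical(res$log_hr, 0)
  expect_identical(res$flagged, "constant covariate")
  ann$event <- 0L
  expect_error(cox_survival(ann, "flat"), "no events")
})

test_that("Cox and log-rank agree in sign; controls are accepted", {
  cfg <- survival_config(1500, hazard_coef = 1.2, seed = 77)
  sim <- simulate_tumor_cohort(cfg)
  ann <- sim$annotations[sim$annotations$class == "tumor", ]
  ann$latent <- sim$truth$latent[ann$sample_id]
  ann$call <- ifelse(sim$truth$pi_status[ann$sample_id], "PI+", "PI-")
  ann$age <- runif(nrow(ann), 40, 80)
  cx <- cox_survival(ann, "latent", controls = "age")
  expect_gt(cx$log_hr, 0)
  expect_lt(cx$p, 0.01)
  km <- km_logrank(ann, "call")
  expect_lt(km$p, 0.01)
  # higher hazard group has the lower KM curve at late times
  late <- max(km$curves$time[km$curves$group == "PI+"])
  s_pos <- min(km$curves$surv[km$curves$group == "PI+"])
  s_neg <- km$curves$surv[km$curves$group == "PI-"]
  s_neg_late <- min(s_neg[km$curves$time[km$curves$group == "PI-"] <= late])
  expect_lt(s_pos, s_neg_late)
  # median ratio PI- / PI+ > 1: PI- patients live longer
  expect_gt(km$median_ratio, 1)
})

test_that("KM product-limit matches a hand-computed 6-record toy", {
  records <- data.frame(
    time = c(1, 3, 5, 2, 4, 6),
    event = c(1, 1, 0, 1, 0, 1),
    call = c("A", "A", "A", "B", "B", "B"))
  km <- km_logrank(records, "call")
  for (g in c("A", "B")) {
    rec <- records[records$call == g, ]
    oracle <- km_oracle(rec$time, rec$event)
    got <- km$curves[km$curves$group == g, ]
    merged <- merge(oracle, got, by = "time")
    expect_equal(merged$surv.x, merged$surv.y, tolerance = 1e-12)
  }
  # identical groups: log-rank p ~ 1
  dup <- rbind(records, transform(records, call = "C"))
  dup$call[dup$call != "C"] <- "D"
  expect_gt(km_logrank(dup, "call")$p, 0.9)
  expect_error(km_logrank(records[records$call == "A", ], "call"),
               "two non-empty groups")
})

test_that("NSAID response: shifted signatures are detected, nulls and
           full ties are handled", {
  set.seed(78)
  bg <- setNames(rnorm(5000, 0, 0.5), sprintf("bg%04d", 1:5000))
  sig_fc <- setNames(rnorm(40, -1, 0.5), sprintf("sig%02d", 1:40))
  res <- nsaid_response_test(c(bg, sig_fc), names(sig_fc))
  expect_lt(res$p, 1e-4)
  expect_gt(res$frac_down, 0.8)
  expect_lt(res$median_shift, 0)

  # null calibration: signature drawn from the background distribution
  pvals <- replicate(200, {
    fc <- setNames(rnorm(2040, 0, 0.5), c(names(bg)[1:2000],
                                          names(sig_fc)))
    nsaid_response_test(fc, names(sig_fc))$p
  })
  expect_lt(abs(mean(pvals < 0.05) - 0.05),
            3 * sqrt(0.05 * 0.95 / 200) + 0.01)

  # complete ties: p defined as 1
  tied <- setNames(rep(0.2, 100), sprintf("g%03d", 1:100))
  expect_identical(nsaid_response_test(tied, sprintf("g%03d", 1:10))$p, 1)

  expect_error(nsaid_response_test(bg, sprintf("nope%d", 1:40)),
               "cover")
  expect_error(nsaid_response_test(unname(bg), names(sig_fc)), "named")
})
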