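# Synthetic cohort generators. All expression is on the log2 scale, genes
# in rows and samples in columns, and every matrix carries the PTPRC (CD45)
# marker row. Each generator returns the matrix (or counts), a sample
# annotation data.frame, and a `truth` list sufficient for downstream
# parameter-recovery tests.

# Linear infiltration model shared by normals and tumors:
# x_{g,s} = baseline_g + slope_{g,t(s)} * cd45_s + eps, eps ~ N(0, noise_sd)
sim_linear_block <- function(universe, tissue, cd45, noise_sd) {
  n <- length(cd45)
  x <- universe$baseline +
    universe$slopes[, tissue, drop = TRUE] %o% cd45 +
    matrix(rnorm(length(universe$genes) * n, 0, noise_sd),
           nrow = length(universe$genes))
  rownames(x) <- universe$genes
  x["PTPRC", ] <- cd45
  x
}

sim_cd45 <- function(config, n) {
  pmax(rnorm(n, config$infiltration_mean, config$infiltration_sd), 0)
}

#' Simulate reference normal tissue (infiltration training data)
#'
#' Emulates a GTEx-like panel of normal samples in which each gene's log2
#' expression depends linearly on CD45 (PTPRC) log2 expression through a
#' gene- and tissue-specific slope, plus Gaussian noise. The CD45 row of
#' the returned matrix equals the simulated infiltration level exactly.
#'
#' @param config a [sim_config()].
#' @return list with `expression` (genes x samples log2 matrix),
#'   `annotations` (sample_id, tissue, class) and `truth` (true slopes,
#'   baselines, per-sample CD45).
#' @export
simulate_reference_normals <- function(config) {
  config <- validate_sim_config(config)
  universe <- sim_universe(config)
  with_sim_seed(config$seed, 1, {
    per <- config$n_reference_per_tissue
    cols <- list()
    ann <- list()
    for (t in universe$tissues) {
      cd45 <- sim_cd45(config, per)
      x <- sim_linear_block(universe, t, cd45, config$noise_sd)
      colnames(x) <- sprintf("%s_normal%03d", t, seq_len(per))
      cols[[t]] <- x
      ann[[t]] <- data.frame(sample_id = colnames(x), tissue = t,
                             class = "normal", stringsAsFactors = FALSE)
    }
    expr <- do.call(cbind, cols)
    annotations <- do.call(rbind, c(ann, list(make.row.names = FALSE)))
    list(expression = expr,
         annotations = annotations,
         truth = list(slopes = universe$slopes,
                      baseline = universe$baseline,
                      cd45 = setNames(expr["PTPRC", ], colnames(expr))))
  })
}

#' Simulate a tumor cohort with adjacent normals
#'
#' Tumors and adjacent normals share the reference infiltration model. A
#' `pi_positive_fraction` subset of tumors activates the PI program: each
#' PI+ tumor adds a per-sample log2 effect to a random
#' Binomial(signature_size, activation_rate) subset of signature genes.
#' Annotations carry p53 status (Bernoulli with logit depending on PI
#' status) and exponential survival with hazard
#' `hazard_base * exp(hazard_coef * latent intensity)` under independent
#' uniform censoring calibrated to `censor_rate`. Survival and p53 status
#' are generated for tumor samples only.
#'
#' @param config a [sim_config()].
#' @return list with `expression`, `annotations` (sample_id, tissue, class,
#'   p53_status, time, event) and `truth` (pi_status, activated_genes,
#'   latent intensity, signature, slopes, hazard_coef).
#' @export
simulate_tumor_cohort <- function(config) {
  config <- validate_sim_config(config)
  universe <- sim_universe(config)
  with_sim_seed(config$seed, 2, {
    blocks <- list()
    ann <- list()
    for (t in universe$tissues) {
      for (cls in c("tumor", "normal")) {
        n <- if (cls == "tumor") config$n_tumors_per_tissue else
          config$n_normals_per_tissue
        if (n == 0) next
        cd45 <- sim_cd45(config, n)
        x <- sim_linear_block(universe, t, cd45, config$noise_sd)
        colnames(x) <- sprintf("%s_%s%03d", t, cls, seq_len(n))
        blocks[[paste(t, cls)]] <- x
        ann[[paste(t, cls)]] <- data.frame(
          sample_id = colnames(x), tissue = t, class = cls,
          stringsAsFactors = FALSE)
      }
    }
    expr <- do.call(cbind, blocks)
    annotations <- do.call(rbind, c(ann, list(make.row.names = FALSE)))

    tumor_ids <- annotations$sample_id[annotations$class == "tumor"]
    n_tum <- length(tumor_ids)
    pi_status <- setNames(
      runif(n_tum) < config$pi_positive_fraction, tumor_ids)

    latent <- setNames(numeric(n_tum), tumor_ids)
    activated <- setNames(vector("list", n_tum), tumor_ids)
    for (s in tumor_ids[pi_status]) {
      n_act <- max(1L, rbinom(1, config$signature_size,
                              config$activation_rate))
      genes <- sample(universe$signature, n_act)
      effect <- max(0, rnorm(1, config$activation_mean,
                             config$activation_sd))
      expr[genes, s] <- expr[genes, s] + effect
      activated[[s]] <- sort(genes)
      latent[s] <- effect * n_act / config$signature_size
    }

    p53 <- setNames(
      runif(n_tum) < plogis(config$p53_intercept +
                              config$p53_coef * as.numeric(pi_status)),
      tumor_ids)

    t_true <- rexp(n_tum, rate = config$hazard_base *
                     exp(config$hazard_coef * latent))
    if (config$censor_rate > 0 && config$censor_rate < 1) {
      cmax <- uniroot(function(m) mean(pmin(t_true / m, 1)) -
                        config$censor_rate,
                      interval = c(min(t_true) * 1e-9, max(t_true) * 1e9),
                      tol = 1e-9)$root
      cens <- runif(n_tum, 0, cmax)
      time <- pmin(t_true, cens)
      event <- as.integer(t_true <= cens)
    } else {
      time <- t_true
      event <- rep(1L, n_tum)
    }

    idx <- match(annotations$sample_id, tumor_ids)
    annotations$p53_status <- ifelse(is.na(idx), NA,
                                     ifelse(p53[idx], "mut", "WT"))
    annotations$time <- ifelse(is.na(idx), NA_real_, time[idx])
    annotations$event <- ifelse(is.na(idx), NA_integer_, event[idx])

    list(expression = expr,
         annotations = annotations,
         truth = list(pi_status = pi_status,
                      activated_genes = activated,
                      latent = latent,
                      p53_status = p53,
                      signature = universe$signature,
                      slopes = universe$slopes,
                      baseline = universe$baseline,
                      hazard_coef = config$hazard_coef))
  })
}

#' Simulate a cell-line expression panel
#'
#' Emulates a CCLE-like panel in which signature genes show a bimodal log2
#' expression pattern — a `bimodal_weight` fraction of lines sit in a high
#' component `bimodal_separation` log2 units above the main mode — while
#' all other genes are unimodal Gaussian. The truth records which lines are
#' in the high component of each bimodal gene.
#'
#' @param config a [sim_config()].
#' @return list with `expression`, `annotations` and `truth`
#'   (`bimodal_genes`, `high_component` logical genes x lines matrix).
#' @export
simulate_cell_line_panel <- function(config) {
  config <- validate_sim_config(config)
  universe <- sim_universe(config)
  with_sim_seed(config$seed, 3, {
    n <- config$n_cell_lines
    ids <- sprintf("line%04d", seq_len(n))
    expr <- universe$baseline +
      matrix(rnorm(length(universe$genes) * n, 0, config$bimodal_sd),
             nrow = length(universe$genes),
             dimnames = list(universe$genes, ids))
    high <- matrix(FALSE, nrow = length(universe$signature), ncol = n,
                   dimnames = list(universe$signature, ids))
    for (g in universe$signature) {
      h <- runif(n) < config$bimodal_weight
      expr[g, h] <- expr[g, h] + config$bimodal_separation
      high[g, ] <- h
    }
    list(expression = expr,
         annotations = data.frame(sample_id = ids, tissue = "cell_line",
                                  class = "cell_line",
                                  stringsAsFactors = FALSE),
         truth = list(bimodal_genes = universe$signature,
                      high_component = high,
                      baseline = universe$baseline))
  })
}

#' Simulate an RNA-seq count experiment with embedded fold changes
#'
#' Emulates a small knockout design (wild type plus two knockout
#' conditions, `counts_n_reps` replicates each) with negative-binomial
#' counts: `counts ~ NB(mean = size_factor * base_mean * 2^lfc,
#' dispersion = nb_dispersion)`. A `counts_de_shared` set of genes is
#' differentially expressed in both knockout conditions and
#' `counts_de_unique` additional genes in each alone; a configurable
#' fraction of DE genes is drawn from a simulated inflammatory-response
#' gene universe so the intersection the signature derivation must recover
#' is known by construction.
#'
#' @param config a [sim_config()].
#' @param conditions condition labels; the first is the reference.
#' @return list with `counts` (integer genes x samples), `conditions`
#'   (data.frame sample_id, condition) and `truth` (`de` table of gene /
#'   condition / lfc, `inflammatory` gene list, `expected_up` /
#'   `expected_down` intersections shared by both non-reference
#'   conditions).
#' @export
simulate_counts <- function(config, conditions = c("WT", "KO_A", "KO_B")) {
  config <- validate_sim_config(config)
  if (length(conditions) < 2) {
    stop("simulate_counts: need a reference and >= 1 test condition",
         call. = FALSE)
  }
  if (config$counts_n_reps < 2) {
    stop("simulate_counts: >= 2 replicates per condition required",
         call. = FALSE)
  }
  with_sim_seed(config$seed, 4, {
    ng <- config$counts_n_genes
    genes <- sprintf("G%05d", seq_len(ng))
    inflammatory <- sort(sample(genes, config$counts_n_inflammatory))

    test_conds <- conditions[-1]
    n_de_total <- config$counts_de_shared +
      config$counts_de_unique * length(test_conds)
    if (n_de_total > ng) {
      stop("simulate_counts: more DE genes requested than genes",
           call. = FALSE)
    }
    # draw DE genes with the configured inflammatory fraction
    n_infl_de <- round(config$counts_frac_de_inflammatory * n_de_total)
    n_infl_de <- min(n_infl_de, length(inflammatory))
    pool <- c(sample(inflammatory, n_infl_de),
              sample(setdiff(genes, inflammatory), n_de_total - n_infl_de))
    pool <- sample(pool)
    shared <- pool[seq_len(config$counts_de_shared)]
    rest <- setdiff(pool, shared)
    unique_sets <- if (config$counts_de_unique > 0) {
      split(rest, rep(seq_along(test_conds),
                      each = config$counts_de_unique))
    } else {
      rep(list(character(0)), length(test_conds))
    }

    sign_of <- function(g) {
      ifelse(runif(length(g)) < config$counts_frac_down, -1, 1)
    }
    shared_lfc <- setNames(config$counts_lfc * sign_of(shared), shared)
    de <- do.call(rbind, lapply(seq_along(test_conds), function(i) {
      uniq <- unique_sets[[i]]
      lfc_u <- setNames(config$counts_lfc * sign_of(uniq), uniq)
      genes_i <- c(shared, uniq)
      data.frame(gene = genes_i,
                 condition = rep(test_conds[i], length(genes_i)),
                 lfc = c(unname(shared_lfc), unname(lfc_u)),
                 stringsAsFactors = FALSE)
    }))

    base_mean <- setNames(rlnorm(ng, meanlog = log(100), sdlog = 1), genes)
    samples <- expand.grid(rep = seq_len(config$counts_n_reps),
                           condition = conditions,
                           stringsAsFactors = FALSE)
    samples$sample_id <- sprintf("%s_rep%d", samples$condition, samples$rep)
    sf <- runif(nrow(samples), 0.7, 1.3)

    counts <- matrix(0L, nrow = ng, ncol = nrow(samples),
                     dimnames = list(genes, samples$sample_id))
    for (j in seq_len(nrow(samples))) {
      lfc <- setNames(numeric(ng), genes)
      hit <- de[de$condition == samples$condition[j], ]
      lfc[hit$gene] <- hit$lfc
      mu <- sf[j] * base_mean * 2^lfc
      counts[, j] <- as.integer(
        rnbinom(ng, mu = mu, size = 1 / config$nb_dispersion))
    }

    in_both <- function(dir) {
      per_cond <- lapply(test_conds, function(cc) {
        d <- de[de$condition == cc, ]
        d$gene[sign(d$lfc) == dir]
      })
      sort(intersect(Reduce(intersect, per_cond), inflammatory))
    }
    list(counts = counts,
         conditions = data.frame(sample_id = samples$sample_id,
                                 condition = samples$condition,
                                 stringsAsFactors = FALSE),
         truth = list(de = de,
                      inflammatory = inflammatory,
                      expected_up = in_both(1),
                      expected_down = in_both(-1)))
  })
}
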