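#' Simulation configuration
#'
#' Bundles every parameter of the synthetic-cohort generators. Defaults
#' reproduce the statistical structure the scoring pipeline assumes: a
#' 40-gene PI signature activated in 25.9% of tumors, a median of 17 of the
#' 40 signature genes activated per PI+ sample, p53-mutation probability
#' rising with PI status (15.2% in PI-, 35.4% in PI+ on the logit scale),
#' immune infiltration encoded as a CD45 (PTPRC) log2-expression row that
#' drives other genes through gene- and tissue-specific linear slopes, and
#' exponential survival with hazard increasing in the latent PI intensity.
#'
#' @param n_genes total genes in the expression universe (includes PTPRC,
#'   GZMA, PRF1 and the signature genes).
#' @param n_tissues number of tissue / cancer types.
#' @param n_reference_per_tissue reference-normal samples per tissue used to
#'   train infiltration slopes.
#' @param n_tumors_per_tissue,n_normals_per_tissue tumor and adjacent-normal
#'   samples per tissue in the cohort generator.
#' @param signature_size number of PI signature genes (default 40).
#' @param pi_positive_fraction fraction of tumors carrying the PI program.
#' @param activation_rate per-gene activation probability within a PI+
#'   sample; Binomial(signature_size, activation_rate) gives the number of
#'   activated genes (mean 17 of 40 by default).
#' @param activation_mean,activation_sd log2 shift added to activated genes
#'   (per-sample effect, truncated at 0).
#' @param infiltration_mean,infiltration_sd CD45 log2-expression
#'   distribution across samples (truncated at 0).
#' @param slope_zero_fraction fraction of (gene, tissue) pairs with no CD45
#'   dependence; the rest get slopes from N(slope_mean, slope_sd).
#' @param slope_mean,slope_sd slope distribution for CD45-dependent genes.
#' @param noise_sd residual log2 sd around the linear model.
#' @param nb_dispersion negative-binomial dispersion of the count simulator.
#' @param p53_intercept,p53_coef logit-scale intercept and PI coefficient of
#'   the mutation model P(mut) = plogis(intercept + coef * pi_status).
#' @param hazard_base,hazard_coef exponential baseline hazard (per day) and
#'   log-hazard increase per unit latent PI intensity.
#' @param censor_rate target fraction of censored survival records
#'   (independent uniform censoring).
#' @param n_cell_lines panel size for the cell-line generator.
#' @param bimodal_weight,bimodal_separation,bimodal_sd mixture weight, log2
#'   separation and component sd of bimodal (signature) genes in the
#'   cell-line panel.
#' @param counts_n_genes,counts_n_reps genes and replicates per condition in
#'   the count simulator.
#' @param counts_lfc absolute log2 fold change embedded in DE genes.
#' @param counts_de_shared DE genes shared by both knockout conditions.
#' @param counts_de_unique additional DE genes private to each condition.
#' @param counts_frac_down fraction of DE genes that are downregulated.
#' @param counts_n_inflammatory size of the simulated inflammatory-response
#'   gene universe.
#' @param counts_frac_de_inflammatory fraction of DE genes drawn from the
#'   inflammatory universe (fixes the intersection sizes the signature
#'   derivation must recover).
#' @param seed integer seed; fixed seed gives byte-identical output.
#'
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_genes = 2000,
                       n_tissues = 3,
                       n_reference_per_tissue = 200,
                       n_tumors_per_tissue = 100,
                       n_normals_per_tissue = 40,
                       signature_size = 40,
                       pi_positive_fraction = 0.259,
                       activation_rate = 17 / 40,
                       activation_mean = 2,
                       activation_sd = 0.5,
                       infiltration_mean = 5,
                       infiltration_sd = 1,
                       slope_zero_fraction = 0.5,
                       slope_mean = 0.5,
                       slope_sd = 0.3,
                       noise_sd = 0.5,
                       nb_dispersion = 0.1,
                       p53_intercept = qlogis(0.152),
                       p53_coef = qlogis(0.354) - qlogis(0.152),
                       hazard_base = 0.001,
                       hazard_coef = 0.8,
                       censor_rate = 0.3,
                       n_cell_lines = 600,
                       bimodal_weight = 0.2,
                       bimodal_separation = 3,
                       bimodal_sd = 0.3,
                       counts_n_genes = 2000,
                       counts_n_reps = 2,
                       counts_lfc = 2.5,
                       counts_de_shared = 60,
                       counts_de_unique = 40,
                       counts_frac_down = 0.25,
                       counts_n_inflammatory = 300,
                       counts_frac_de_inflammatory = 0.5,
                       seed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  counts <- c("n_genes", "n_tissues", "n_reference_per_tissue",
              "n_tumors_per_tissue", "n_normals_per_tissue",
              "signature_size", "n_cell_lines", "counts_n_genes",
              "counts_n_reps")
  for (f in counts) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v <= 0 ||
        v != round(v)) {
      stop("sim_config: `", f, "` must be a positive integer", call. = FALSE)
    }
  }
  props <- c("pi_positive_fraction", "activation_rate",
             "slope_zero_fraction", "censor_rate", "bimodal_weight",
             "counts_frac_down", "counts_frac_de_inflammatory")
  for (f in props) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v > 1) {
      stop("sim_config: `", f, "` must be a proportion in [0, 1]",
           call. = FALSE)
    }
  }
  nonneg <- c("activation_sd", "infiltration_sd", "slope_sd", "noise_sd",
              "nb_dispersion", "bimodal_sd")
  for (f in nonneg) {
    if (cfg[[f]] < 0) {
      stop("sim_config: `", f, "` must be non-negative", call. = FALSE)
    }
  }
  if (cfg$hazard_base <= 0) {
    stop("sim_config: `hazard_base` must be positive", call. = FALSE)
  }
  if (cfg$n_genes < cfg$signature_size + 3) {
    stop("sim_config: `n_genes` must exceed signature_size + marker genes",
         call. = FALSE)
  }
  if (is.na(cfg$seed) || !is.numeric(cfg$seed)) {
    stop("sim_config: `seed` must be an integer", call. = FALSE)
  }
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat("  genes:", x$n_genes, " signature:", x$signature_size,
      " tissues:", x$n_tissues, "\n")
  cat("  tumors/tissue:", x$n_tumors_per_tissue,
      " normals/tissue:", x$n_normals_per_tissue,
      " PI+ fraction:", x$pi_positive_fraction, "\n")
  cat("  seed:", x$seed, "\n")
  invisible(x)
}

# Deterministic gene universe shared by all generators for a given seed:
# gene names, per-gene baselines and per-(gene, tissue) CD45 slopes.
# PTPRC is its own infiltration readout (baseline 0, slope 1, no noise).
sim_universe <- function(config) {
  validate_sim_config(config)
  sig <- sprintf("PI%02d", seq_len(config$signature_size))
  n_bg <- config$n_genes - config$signature_size - 3L
  genes <- c("PTPRC", sig, "GZMA", "PRF1",
             if (n_bg > 0) sprintf("BG%05d", seq_len(n_bg)))
  tissues <- sprintf("tissue%02d", seq_len(config$n_tissues))
  with_sim_seed(config$seed, 0, {
    baseline <- setNames(runif(length(genes), 2, 10), genes)
    baseline["PTPRC"] <- 0
    slopes <- matrix(0, nrow = length(genes), ncol = length(tissues),
                     dimnames = list(genes, tissues))
    for (t in tissues) {
      nz <- runif(length(genes)) >= config$slope_zero_fraction
      slopes[nz, t] <- rnorm(sum(nz), config$slope_mean, config$slope_sd)
    }
    slopes["PTPRC", ] <- 1
    list(genes = genes, signature = sig, tissues = tissues,
         baseline = baseline, slopes = slopes)
  })
}
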