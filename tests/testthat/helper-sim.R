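# Shared small fixtures, built in code. Sizes are kept small; the
# statistical tests that need power use their own larger configs.

small_config <- function(n_genes = 200, seed = 101, ...) {
  sim_config(n_genes = n_genes, n_tissues = 2,
             n_reference_per_tissue = 50, n_tumors_per_tissue = 60,
             n_normals_per_tissue = 30, counts_n_genes = 400,
             seed = seed, ...)
}

# cohort config with a tiny gene universe, for survival / association
# tests where only the truth latents matter
survival_config <- function(n_tumors, seed = 202, ...) {
  sim_config(n_genes = 50, n_tissues = 1, n_reference_per_tissue = 20,
             n_tumors_per_tissue = n_tumors, n_normals_per_tissue = 1,
             seed = seed, ...)
}

# independent product-limit (Kaplan-Meier) oracle: a direct loop over
# event times, no survival:: machinery
km_oracle <- function(time, event) {
  ord <- order(time)
  time <- time[ord]
  event <- event[ord]
  s <- 1
  out <- data.frame(time = numeric(0), surv = numeric(0))
  for (t in unique(time)) {
    at_risk <- sum(time >= t)
    d <- sum(time == t & event == 1)
    s <- s * (1 - d / at_risk)
    out <- rbind(out, data.frame(time = t, surv = s))
  }
  out
}
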