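# Shared fixtures built in code. Expensive simulations are cached per test
# run so several tests can share one realisation.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

## A small fully-simulated study with default (null-interaction) effects.
small_study <- function() {
  cached("small_study", {
    sim <- simulate_study(n_subjects = 150, seed = 42)
    sim$apanel <- prepare_analysis_panel(sim$panel, sim$exposures)
    sim
  })
}

## One-outcome study with a planted SBP x PM10 interaction at a single SNP.
planted_interaction_study <- function(beta_int = 2, n = 400, seed = 101) {
  key <- sprintf("planted_%g_%d_%d", beta_int, n, seed)
  cached(key, {
    eff <- list(sbp = effect_spec(
      "sbp", "pm10", intercept = 131.8, main_effect = 0.93,
      interaction_per_risk_allele = beta_int,
      interacting_snps = data.frame(snp_id = "rs4680",
                                    orientation = "minor_is_risk"),
      random_intercept_sd = 8, residual_sd = 8))
    sim <- simulate_study(n_subjects = n, seed = seed, effects = eff)
    sim$apanel <- prepare_analysis_panel(sim$panel, sim$exposures,
                                         pollutants = "pm10")
    sim
  })
}

## Screen of the planted-interaction study (shared across test files).
planted_screen <- function() {
  cached("planted_screen", {
    sim <- planted_interaction_study(beta_int = 2, n = 400, seed = 101)
    screen_all(sim$apanel, sim$genotypes, pollutants = "pm10",
               bp_outcomes = "sbp", hrv_outcomes = character(0))
  })
}

## Simple exposure series with deterministic values, for lag arithmetic.
toy_series <- function(values, start = as.Date("2020-01-01")) {
  data.frame(date = start + seq_along(values) - 1,
             pm10 = values, no2 = values, so2 = values,
             mean_temp = rep(10, length(values)),
             dew_point = rep(0, length(values)))
}

## Genotype table built directly from a genotype matrix.
toy_genotypes <- function(mat, genes = NULL) {
  if (is.null(genes)) genes <- rep("G1", ncol(mat))
  structure(list(
    genotypes = mat,
    snp_info = data.frame(snp_id = colnames(mat), gene = genes,
                          maf = colMeans(mat, na.rm = TRUE) / 2,
                          stringsAsFactors = FALSE)),
    class = "genotype_table")
}
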