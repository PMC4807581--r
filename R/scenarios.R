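## Canned simulation scenarios for the two headline in-silico analyses:
## effect-modification of the air pollution / HRV association by a genetic
## risk score, and selection bias from non-random dropout corrected by IPW.

#' Effect-modification scenario for log-SDNN
#'
#' Ten unlinked SNPs of the default panel carry a planted interaction of
#' -0.03 log-SDNN per IQR per risk allele (minor allele adverse). The
#' pollutant main effect is set to `+0.03 * E[G]` (with `E[G]` the expected
#' risk-allele count of the panel) so the marginal whole-cohort association
#' cancels at the mean risk score: the cohort-level association is null
#' while the low and high risk-score tertiles show opposite-signed effects —
#' the qualitative signature the stratified analysis is designed to expose.
#'
#' @return List with `effects` (for [simulate_panel_outcomes()]), `panel`
#'   (`data.frame(snp_id, orientation)` of the planted SNPs) and
#'   `beta_int` (the planted per-allele interaction).
#' @export
scenario_hrv_modification <- function() {
  tab <- default_snp_table()
  blocked <- unlist(lapply(default_ld_blocks(), `[[`, "snp_ids"))
  cand <- setdiff(tab$snp_id[!tab$hwe_violation], blocked)[1:10]
  mafs <- tab$maf[match(cand, tab$snp_id)]
  eg <- sum(2 * mafs)
  panel <- data.frame(snp_id = cand, orientation = "minor_is_risk",
                      stringsAsFactors = FALSE)
  beta_int <- -0.03
  effects <- list(
    sdnn = effect_spec("sdnn", "pm10", intercept = log(26.9),
                       main_effect = -beta_int * eg,
                       interaction_per_risk_allele = beta_int,
                       interacting_snps = panel,
                       random_intercept_sd = 0.38, residual_sd = 0.37))
  list(effects = effects, panel = panel, beta_int = beta_int,
       expected_g = eg)
}

#' Non-random dropout scenario for the IPW sensitivity analysis
#'
#' Systolic BP is generated with subject-level heterogeneity in the per-IQR
#' pollutant slope (SD 2 mmHg per IQR, correlation 0.7 with the BP random
#' intercept — pollution-responsive subjects tend to run higher pressures),
#' and follow-up retention drops with the prior visit's SBP (logit slope
#' -0.05 per mmHg, intercept calibrated to roughly 75 percent retention per
#' visit at the mean). Because dropout selects on the prior outcome while
#' slopes vary between subjects, the unweighted random-intercept fit is
#' biased toward the slopes of the retained; weighting follow-ups by the
#' inverse fitted retention probability (prior BP among the predictors)
#' moves the estimate back toward the population value.
#'
#' @param beta_main Generating population-average slope (mmHg per IQR),
#'   default 1.0.
#' @return List with `effects`, `dropout` (a [dropout_spec()]) and
#'   `beta_main`.
#' @export
scenario_ipw_dropout <- function(beta_main = 1.0) {
  effects <- list(
    sbp = effect_spec("sbp", "pm10", intercept = 131.8,
                      main_effect = beta_main,
                      random_intercept_sd = 12, residual_sd = 10,
                      random_slope_sd = 2, slope_intercept_cor = 0.7))
  dropout <- dropout_spec("MAR", c(intercept = 1.2 + 0.05 * 131.8,
                                   sbp = -0.05))
  list(effects = effects, dropout = dropout, beta_main = beta_main)
}
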