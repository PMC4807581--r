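test_that("with no between-subject variance the mixed fit matches OLS", {
  eff <- list(sbp = effect_spec("sbp", "pm10", intercept = 120,
                                main_effect = 2,
                                covariate_effects = c(age = 0.2, bmi = 0.3),
                                random_intercept_sd = 0, residual_sd = 6))
  sim <- simulate_study(n_subjects = 250, seed = 55, effects = eff)
  ap <- prepare_analysis_panel(sim$panel, sim$exposures,
                               pollutants = "pm10")
  sp <- model_spec("sbp", "pm10", lag = 0)
  f <- fit_main_model(ap, sp)
  expect_lt(as.numeric(lme4::VarCorr(f$model)$subject_id[1]), 0.5)
  d <- ap
  d$poll_iqr <- d$pm10_lag0 / f$iqr
  ols <- lm(sbp ~ age + sex + smoking + alcohol + bmi + htn_med +
              atemp_lag0 + poll_iqr, data = d)
  expect_lt(abs(f$estimate - coef(ols)[["poll_iqr"]]), 1e-3)
})

test_that("per-IQR coefficient equals per-unit coefficient times the IQR", {
  sim <- small_study()
  sp <- model_spec("sbp", "pm10", lag = 0)
  f_iqr <- fit_main_model(sim$apanel, sp)
  f_unit <- fit_main_model(sim$apanel, sp, iqr = 1)
  expect_equal(f_iqr$estimate, f_unit$estimate * f_iqr$iqr,
               tolerance = 1e-6)
  ## same observation set for both
  expect_equal(f_iqr$n_obs, f_unit$n_obs)
})

test_that("fit results expose coefficients, CI arithmetic and model size", {
  sim <- small_study()
  f <- fit_main_model(sim$apanel, model_spec("log_sdnn", "no2", lag = 1))
  tab <- coef(f)
  expect_true(all(c("estimate", "se", "p", "ci_low", "ci_high")
                  %in% names(tab)))
  expect_equal(f$ci, c(f$estimate - 1.96 * f$se, f$estimate + 1.96 * f$se))
  expect_equal(f$aic, 2 * attr(logLik(f$model), "df") - 2 * f$loglik,
               tolerance = 1e-9)
  expect_equal(f$n_subjects, length(unique(sim$panel$subject_id)))
  expect_output(print(f), "effect per IQR")
})

test_that("AIC lag selection recovers a strongly planted lag", {
  eff <- list(sbp = effect_spec("sbp", "pm10", intercept = 131.8,
                                main_effect = 8, true_lag = 2,
                                random_intercept_sd = 8, residual_sd = 8))
  hits <- vapply(1:10, function(r) {
    sim <- simulate_study(n_subjects = 200, seed = 300 + r, effects = eff)
    ap <- prepare_analysis_panel(sim$panel, sim$exposures,
                                 pollutants = "pm10")
    select_lag(ap, model_spec("sbp", "pm10"))$lag == 2L
  }, TRUE)
  expect_gte(mean(hits), 0.8)
})

test_that("lag-selection ties break to the smallest lag", {
  ## series constant within 4-day stretches: lags 0-3 are identical columns
  vals <- rep(seq(20, 80, by = 4), each = 4)
  s <- toy_series(vals)
  sim <- small_study()
  sched <- simulate_visit_schedule(80, n_visits = 4,
                                   start_date = s$date[12],
                                   span_days = as.integer(
                                     s$date[length(vals) - 8] - s$date[12]),
                                   jitter_days = 6, seed = 2)
  ## snap visits to stretch-final days so every lag hits the same stretch
  off <- as.integer(sched$date - s$date[1]) %% 4
  sched$date <- sched$date + (3 - off)
  eff <- list(sbp = effect_spec("sbp", "pm10", intercept = 120,
                                main_effect = 1, random_intercept_sd = 5,
                                residual_sd = 5))
  gt <- simulate_genotypes(80, list(snp_spec("s1", "G", 0.3)), seed = 3)
  panel <- simulate_panel_outcomes(gt, s, sched, effects = eff, seed = 4)
  ap <- prepare_analysis_panel(panel, s, pollutants = "pm10")
  expect_equal(ap$pm10_lag0, ap$pm10_lag3)
  sel <- select_lag(ap, model_spec("sbp", "pm10"))
  expect_equal(sel$lag, 0L)
  expect_equal(max(sel$aic) - min(sel$aic), 0, tolerance = 1e-6)
})

test_that("a planted interaction is recovered with correct orientation", {
  sim <- planted_interaction_study(beta_int = 2, n = 400, seed = 101)
  r <- test_snp_interaction(sim$apanel, sim$genotypes,
                            model_spec("sbp", "pm10", lag = 0,
                                       snp_id = "rs4680"), joint = TRUE)
  expect_false(r$skipped)
  expect_lt(abs(r$beta_interaction - 2), 3 * r$se)
  expect_equal(r$risk_allele_orientation, "minor_is_risk")
  expect_lt(r$p_interaction, 0.05)
  expect_lt(r$p_joint_2df, 0.05)
  ## Wald z^2 approximates the 1-df LRT for the same term
  r_lrt <- test_snp_interaction(sim$apanel, sim$genotypes,
                                model_spec("sbp", "pm10", lag = 0,
                                           snp_id = "rs4680"), test = "lrt")
  z2 <- (r$beta_interaction / r$se)^2
  lrt1 <- qchisq(r_lrt$p_interaction, 1, lower.tail = FALSE)
  expect_lt(abs(z2 - lrt1) / lrt1, 0.15)
})

test_that("orientation flips with the interaction sign and outcome family", {
  sim <- planted_interaction_study(beta_int = -2, n = 400, seed = 102)
  r <- test_snp_interaction(sim$apanel, sim$genotypes,
                            model_spec("sbp", "pm10", lag = 0,
                                       snp_id = "rs4680"))
  expect_equal(r$risk_allele_orientation, "major_is_risk")
})

test_that("monomorphic SNPs are skipped with a log entry", {
  sim <- small_study()
  g <- sim$genotypes
  g$genotypes <- cbind(g$genotypes, mono = 0L)
  g$snp_info <- rbind(g$snp_info,
                      data.frame(snp_id = "mono", gene = "G", maf = 0))
  expect_message(
    r <- test_snp_interaction(sim$apanel, g,
                              model_spec("sbp", "pm10", lag = 0,
                                         snp_id = "mono")),
    "monomorphic")
  expect_true(r$skipped)
})

test_that("the 2-df joint test refuses mismatched observation sets", {
  sim <- small_study()
  sp <- model_spec("sbp", "pm10", lag = 0)
  f1 <- fit_main_model(sim$apanel, sp)
  f2 <- fit_main_model(sim$apanel[-(1:5), ], sp)
  expect_error(panelgxe:::lrt_2df(f1$model, f2$model),
               "different observation sets")
  jt <- joint_2df_test(sim$apanel, sim$genotypes,
                       model_spec("sbp", "pm10", lag = 0,
                                  snp_id = "rs4680"))
  expect_gte(jt$lrt, 0)
  expect_equal(jt$df, 2L)
  expect_true(jt$p > 0 && jt$p <= 1)
})

test_that("screen_all flags planted SNPs and returns both candidate sets", {
  sim <- planted_interaction_study(beta_int = 2, n = 400, seed = 101)
  sc <- planted_screen()
  expect_true("rs4680" %in% sc$bp_snps)
  expect_equal(nrow(sc$results), ncol(sim$genotypes$genotypes))
  ## alpha = 1 flags every testable SNP
  keep <- c("rs4680", "rs1695", "rs662")
  gsub <- sim$genotypes
  gsub$genotypes <- gsub$genotypes[, keep]
  gsub$snp_info <- gsub$snp_info[gsub$snp_info$snp_id %in% keep, ]
  sc1 <- screen_all(sim$apanel, gsub, pollutants = "pm10",
                    bp_outcomes = "sbp", hrv_outcomes = character(0),
                    alpha = 1)
  testable <- sc1$results$snp_id[!sc1$results$skipped]
  expect_setequal(sc1$bp_snps, testable)
})
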