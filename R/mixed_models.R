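## Linear mixed models for the panel: pollutant main-effect models, per-SNP
## interaction models, AIC lag selection, 2-df joint LRT, full screening.
## All fits use maximum likelihood (REML = FALSE) because AIC comparisons
## across fixed-effect structures and the likelihood-ratio tests require it.

default_covariates <- function()
  c("age", "sex", "smoking", "alcohol", "bmi", "htn_med")

#' Model specification for one outcome-pollutant analysis
#'
#' @param outcome Outcome column (`"sbp"`, `"dbp"`, `"map"` or a `log_*`
#'   HRV column).
#' @param pollutant Pollutant (`"pm10"`, `"no2"`, `"so2"`).
#' @param lag Lag in days (0-3), or `NULL` before lag selection.
#' @param covariates A-priori covariate columns; apparent temperature (at
#'   the pollutant's lag) is always added.
#' @param snp_id Optional SNP for interaction models.
#' @return An object of class `gxe_model_spec`.
#' @export
model_spec <- function(outcome, pollutant, lag = NULL,
                       covariates = default_covariates(), snp_id = NULL) {
  structure(list(outcome = outcome, pollutant = pollutant, lag = lag,
                 covariates = covariates, snp_id = snp_id),
            class = "gxe_model_spec")
}

outcome_family <- function(outcome) {
  if (outcome %in% c("sbp", "dbp", "map")) "blood_pressure"
  else if (grepl("^log_", outcome)) "heart_rate_variability"
  else stop_cfg("unknown outcome %s", outcome)
}

lag_col <- function(prefix, lag) sprintf("%s_lag%d", prefix, lag)

## Shared preparation: complete cases over the columns a fit needs, and the
## per-IQR pollutant column. IQR is computed over distinct survey days of
## the analysis rows unless an iqr value is imposed (stratified fits impose
## the whole-cohort IQR so estimates stay comparable across strata).
prep_fit_data <- function(panel, spec, extra_cols = character(0),
                          iqr = NULL, weights = NULL) {
  if (is.null(spec$lag)) stop_cfg("model spec has no lag; run select_lag()")
  pcol <- lag_col(spec$pollutant, spec$lag)
  acol <- lag_col("atemp", spec$lag)
  need <- c(spec$outcome, spec$covariates, pcol, acol, "subject_id", "date",
            extra_cols)
  miss <- setdiff(need, names(panel))
  if (length(miss)) stop_cfg("panel lacks required column(s): %s",
                             paste(miss, collapse = ", "))
  if (!is.null(weights)) {
    stopifnot(length(weights) == nrow(panel))
    panel$.ipw_w <- weights
    need <- c(need, ".ipw_w")
  }
  d <- panel[complete.cases(panel[, need, drop = FALSE]), need, drop = FALSE]
  if (is.null(iqr))
    iqr <- iqr_scale(d[[pcol]][!duplicated(d$date)])$iqr
  d$poll_iqr <- d[[pcol]] / iqr
  list(data = d, iqr = iqr, atemp_col = acol)
}

fit_lmm <- function(d, outcome, fixed_terms, use_weights = FALSE) {
  fml <- as.formula(paste(outcome, "~", paste(fixed_terms, collapse = " + "),
                          "+ (1 | subject_id)"))
  ctrl <- lme4::lmerControl(calc.derivs = FALSE,
                            check.conv.singular = "ignore")
  if (use_weights)
    lme4::lmer(fml, data = d, REML = FALSE, weights = .ipw_w, control = ctrl)
  else
    lme4::lmer(fml, data = d, REML = FALSE, control = ctrl)
}

fe_table <- function(model) {
  est <- lme4::fixef(model)
  se <- sqrt(diag(as.matrix(vcov(model))))
  z <- est / se
  data.frame(term = names(est), estimate = unname(est), se = unname(se),
             z = unname(z), p = 2 * pnorm(-abs(unname(z))),
             ci_low = unname(est - 1.96 * se),
             ci_high = unname(est + 1.96 * se),
             stringsAsFactors = FALSE, row.names = NULL)
}

model_converged <- function(model) {
  msgs <- model@optinfo$conv$lme4$messages
  is.null(msgs) || !any(grepl("fail|unable", msgs, ignore.case = TRUE))
}

#' Fit the pollutant main-effect linear mixed model
#'
#' Fixed effects: the a-priori covariates, apparent temperature at the
#' pollutant's lag, and the IQR-scaled lagged pollutant; a random intercept
#' per subject; maximum-likelihood estimation. The pollutant coefficient is
#' reported per IQR increase with a Wald 95 percent CI.
#'
#' @param panel Analysis panel from [prepare_analysis_panel()].
#' @param spec A [model_spec()] with `lag` set.
#' @param iqr Optional externally imposed IQR (pollutant units).
#' @param weights Optional observation weights aligned to `panel` rows
#'   (inverse-probability-of-follow-up weighting).
#' @return A `gxe_fit` object.
#' @export
fit_main_model <- function(panel, spec, iqr = NULL, weights = NULL) {
  pd <- prep_fit_data(panel, spec, iqr = iqr, weights = weights)
  m <- fit_lmm(pd$data, spec$outcome,
               c(spec$covariates, pd$atemp_col, "poll_iqr"),
               use_weights = !is.null(weights))
  if (!model_converged(m))
    stop_cfg("mixed model failed to converge for %s ~ %s lag %d",
             spec$outcome, spec$pollutant, spec$lag)
  tab <- fe_table(m)
  prow <- tab[tab$term == "poll_iqr", ]
  structure(list(model = m, coefficients = tab,
                 outcome = spec$outcome, pollutant = spec$pollutant,
                 lag = spec$lag, iqr = pd$iqr,
                 estimate = prow$estimate, se = prow$se, p = prow$p,
                 ci = c(prow$ci_low, prow$ci_high),
                 loglik = as.numeric(logLik(m)), aic = AIC(m),
                 n_obs = nrow(pd$data),
                 n_subjects = length(unique(pd$data$subject_id)),
                 converged = TRUE, weighted = !is.null(weights)),
            class = "gxe_fit")
}

#' @export
print.gxe_fit <- function(x, ...) {
  cat(sprintf("Linear mixed model (ML): %s ~ %s (lag %d)%s\n", x$outcome,
              x$pollutant, x$lag, if (x$weighted) ", IPW-weighted" else ""))
  cat(sprintf("  %d observations of %d subjects; pollutant IQR = %.2f\n",
              x$n_obs, x$n_subjects, x$iqr))
  cat(sprintf("  effect per IQR: %.3f (95%% CI %.3f, %.3f), p = %.3g\n",
              x$estimate, x$ci[1], x$ci[2], x$p))
  invisible(x)
}

#' @export
coef.gxe_fit <- function(object, ...) object$coefficients

#' @export
summary.gxe_fit <- function(object, ...) {
  print(object)
  print(object$coefficients, digits = 3)
  invisible(object$coefficients)
}

#' Select the best-fitting lag by AIC
#'
#' Fits the main model at every lag 0..`max_lag` on the *identical*
#' observation set (complete cases across all lags) and returns the
#' minimum-AIC lag; ties break to the smallest lag. Non-convergent lags are
#' excluded from the comparison with a warning.
#'
#' @param panel Analysis panel.
#' @param spec A [model_spec()] (its `lag` is ignored).
#' @param max_lag Maximum lag (default 3).
#' @return List with `lag` (selected), `aic` (named per-lag AIC vector,
#'   `NA` for excluded lags), and `fit` (the selected `gxe_fit`).
#' @export
select_lag <- function(panel, spec, max_lag = 3) {
  all_cols <- c(vapply(0:max_lag, function(k) lag_col(spec$pollutant, k), ""),
                vapply(0:max_lag, function(k) lag_col("atemp", k), ""),
                spec$outcome, spec$covariates, "subject_id", "date")
  miss <- setdiff(all_cols, names(panel))
  if (length(miss)) stop_cfg("panel lacks required column(s): %s",
                             paste(miss, collapse = ", "))
  d <- panel[complete.cases(panel[, all_cols, drop = FALSE]), , drop = FALSE]
  fits <- vector("list", max_lag + 1)
  aic <- setNames(rep(NA_real_, max_lag + 1), paste0("lag", 0:max_lag))
  for (k in 0:max_lag) {
    sk <- spec; sk$lag <- k
    f <- tryCatch(fit_main_model(d, sk), error = function(e) NULL)
    if (is.null(f)) {
      warning(sprintf("lag %d excluded from AIC comparison (no fit)", k))
    } else {
      fits[[k + 1]] <- f
      aic[k + 1] <- f$aic
    }
  }
  if (all(is.na(aic))) stop_cfg("no lag model converged")
  best <- unname(which.min(aic))   # first minimum -> smallest lag on ties
  list(lag = best - 1L, aic = aic, fit = fits[[best]])
}

## Merge one SNP's additive genotype onto panel rows by subject id.
attach_genotype <- function(panel, genotypes, snp_id) {
  if (!snp_id %in% colnames(genotypes$genotypes))
    stop_cfg("SNP %s not in genotype table", snp_id)
  g <- genotypes$genotypes[, snp_id]
  panel$snp_dose <- unname(g[panel$subject_id])
  panel
}

#' Test one SNP x pollutant interaction
#'
#' Adds the additive-coded SNP and its product with the IQR-scaled pollutant
#' to the main model and reports the Wald test of the interaction
#' coefficient. The risk-allele orientation is `minor_is_risk` when the
#' interaction points in the adverse direction (positive for BP outcomes,
#' negative for log-HRV outcomes), else `major_is_risk`.
#'
#' @param panel Analysis panel.
#' @param genotypes A `genotype_table`.
#' @param spec A [model_spec()] with `snp_id` and `lag` set.
#' @param joint Also run the 2-df joint likelihood-ratio test of the SNP
#'   main effect and interaction (default `FALSE`).
#' @param test `"wald"` (default) or `"lrt"` for the 1-df interaction
#'   p-value.
#' @return An `interaction_result` (list); monomorphic SNPs give a result
#'   with `skipped = TRUE`.
#' @export
test_snp_interaction <- function(panel, genotypes, spec, joint = FALSE,
                                 test = c("wald", "lrt")) {
  test <- match.arg(test)
  if (is.null(spec$snp_id)) stop_cfg("spec$snp_id is required")
  panel <- attach_genotype(panel, genotypes, spec$snp_id)
  pd <- prep_fit_data(panel, spec, extra_cols = "snp_dose")
  base <- list(snp_id = spec$snp_id, pollutant = spec$pollutant,
               outcome = spec$outcome, lag = spec$lag)
  if (length(unique(pd$data$snp_dose)) < 2) {
    message(sprintf("SNP %s monomorphic in the analysis sample; skipped",
                    spec$snp_id))
    return(structure(c(base, list(skipped = TRUE)),
                     class = "interaction_result"))
  }
  covs <- c(spec$covariates, pd$atemp_col)
  full <- fit_lmm(pd$data, spec$outcome,
                  c(covs, "poll_iqr", "snp_dose", "poll_iqr:snp_dose"))
  tab <- fe_table(full)
  irow <- tab[tab$term == "poll_iqr:snp_dose", ]
  p_int <- irow$p
  if (test == "lrt") {
    red <- fit_lmm(pd$data, spec$outcome, c(covs, "poll_iqr", "snp_dose"))
    lrt <- max(0, 2 * (as.numeric(logLik(full)) - as.numeric(logLik(red))))
    p_int <- pchisq(lrt, df = 1, lower.tail = FALSE)
  }
  adverse_positive <- outcome_family(spec$outcome) == "blood_pressure"
  orientation <- if (irow$estimate == 0) NA_character_
    else if ((irow$estimate > 0) == adverse_positive) "minor_is_risk"
    else "major_is_risk"
  res <- c(base, list(
    beta_interaction = irow$estimate, se = irow$se, p_interaction = p_int,
    ci = c(irow$ci_low, irow$ci_high),
    risk_allele_orientation = orientation,
    n_obs = nrow(pd$data), skipped = FALSE, model = full))
  if (joint) {
    nested <- fit_lmm(pd$data, spec$outcome, c(covs, "poll_iqr"))
    jt <- lrt_2df(full, nested)
    res$lrt_2df <- jt$lrt
    res$p_joint_2df <- jt$p
  }
  structure(res, class = "interaction_result")
}

#' @export
print.interaction_result <- function(x, ...) {
  if (isTRUE(x$skipped)) {
    cat(sprintf("%s x %s on %s: skipped (monomorphic)\n",
                x$snp_id, x$pollutant, x$outcome))
    return(invisible(x))
  }
  cat(sprintf("%s x %s on %s (lag %d): beta_int = %.4f (SE %.4f), p = %.3g, %s\n",
              x$snp_id, x$pollutant, x$outcome, x$lag, x$beta_interaction,
              x$se, x$p_interaction, x$risk_allele_orientation))
  if (!is.null(x$p_joint_2df))
    cat(sprintf("  2-df joint LRT = %.3f, p = %.3g\n", x$lrt_2df,
                x$p_joint_2df))
  invisible(x)
}

lrt_2df <- function(full, nested) {
  if (stats::nobs(full) != stats::nobs(nested))
    stop_cfg("full and nested models use different observation sets (%d vs %d)",
             stats::nobs(full), stats::nobs(nested))
  lrt <- 2 * (as.numeric(logLik(full)) - as.numeric(logLik(nested)))
  if (lrt < -1e-6)
    stop_cfg("negative LRT (%.4g): models are not nested as fitted", lrt)
  lrt <- max(0, lrt)
  list(lrt = lrt, df = 2L, p = pchisq(lrt, df = 2, lower.tail = FALSE))
}

#' 2-df joint likelihood-ratio test of SNP main effect and interaction
#'
#' Compares a full ML model (covariates + pollutant + SNP + SNP x pollutant)
#' with a nested model excluding both SNP terms, on the identical
#' observation set; the statistic is referred to chi-square with 2 df.
#'
#' @inheritParams test_snp_interaction
#' @return List with `lrt`, `df` (2) and `p`.
#' @export
joint_2df_test <- function(panel, genotypes, spec) {
  panel <- attach_genotype(panel, genotypes, spec$snp_id)
  pd <- prep_fit_data(panel, spec, extra_cols = "snp_dose")
  covs <- c(spec$covariates, pd$atemp_col)
  full <- fit_lmm(pd$data, spec$outcome,
                  c(covs, "poll_iqr", "snp_dose", "poll_iqr:snp_dose"))
  nested <- fit_lmm(pd$data, spec$outcome, c(covs, "poll_iqr"))
  lrt_2df(full, nested)
}

#' Screen every SNP x pollutant x outcome combination
#'
#' For each outcome-pollutant pair the lag is selected once by AIC on the
#' main model and reused for all SNP models of that pair. A SNP is
#' interaction-positive for an outcome family when any of its tests within
#' the family reaches `p < alpha` (unadjusted, mirroring a hypothesis-
#' generating screen).
#'
#' @param panel Analysis panel from [prepare_analysis_panel()].
#' @param genotypes A `genotype_table` (after QC).
#' @param pollutants Pollutants to screen.
#' @param bp_outcomes,hrv_outcomes Outcome columns per family.
#' @param alpha Screening threshold (default 0.05).
#' @param joint Also compute the 2-df joint test per combination.
#' @param covariates Covariate set for all models.
#' @return A `gxe_screen` object: `results` (one row per combination),
#'   `lags` (selected lag per outcome-pollutant), `bp_snps`, `hrv_snps`
#'   (interaction-positive sets), `alpha`.
#' @export
screen_all <- function(panel, genotypes, pollutants = c("pm10", "no2", "so2"),
                       bp_outcomes = c("sbp", "dbp", "map"),
                       hrv_outcomes = c("log_sdnn", "log_rmssd", "log_lf",
                                        "log_hf"),
                       alpha = 0.05, joint = FALSE,
                       covariates = default_covariates()) {
  outcomes <- c(bp_outcomes, hrv_outcomes)
  snp_ids <- colnames(genotypes$genotypes)
  lags <- list()
  rows <- list()
  for (out in outcomes) {
    for (poll in pollutants) {
      sel <- select_lag(panel, model_spec(out, poll, covariates = covariates))
      lags[[paste(out, poll, sep = ".")]] <- sel$lag
      for (id in snp_ids) {
        sp <- model_spec(out, poll, lag = sel$lag, covariates = covariates,
                         snp_id = id)
        r <- test_snp_interaction(panel, genotypes, sp, joint = joint)
        rows[[length(rows) + 1]] <- if (isTRUE(r$skipped))
          data.frame(snp_id = id, pollutant = poll, outcome = out,
                     lag = sel$lag, beta_interaction = NA_real_,
                     se = NA_real_, p_interaction = NA_real_,
                     ci_low = NA_real_, ci_high = NA_real_,
                     orientation = NA_character_,
                     p_joint_2df = NA_real_, n_obs = NA_integer_,
                     skipped = TRUE, stringsAsFactors = FALSE)
        else
          data.frame(snp_id = id, pollutant = poll, outcome = out,
                     lag = r$lag, beta_interaction = r$beta_interaction,
                     se = r$se, p_interaction = r$p_interaction,
                     ci_low = r$ci[1], ci_high = r$ci[2],
                     orientation = r$risk_allele_orientation,
                     p_joint_2df = r$p_joint_2df %||% NA_real_,
                     n_obs = r$n_obs, skipped = FALSE,
                     stringsAsFactors = FALSE)
      }
    }
  }
  results <- do.call(rbind, rows)
  positive <- function(fam_outcomes) {
    sub <- results[results$outcome %in% fam_outcomes & !results$skipped, ]
    sort(unique(sub$snp_id[sub$p_interaction < alpha]))
  }
  structure(list(results = results, lags = lags,
                 bp_snps = positive(bp_outcomes),
                 hrv_snps = positive(hrv_outcomes), alpha = alpha,
                 bp_outcomes = bp_outcomes, hrv_outcomes = hrv_outcomes),
            class = "gxe_screen")
}

#' @export
print.gxe_screen <- function(x, ...) {
  cat(sprintf("Interaction screen: %d tests (alpha = %g)\n",
              sum(!x$results$skipped), x$alpha))
  cat(sprintf("  BP-positive SNPs (%d): %s\n", length(x$bp_snps),
              paste(x$bp_snps, collapse = ", ")))
  cat(sprintf("  HRV-positive SNPs (%d): %s\n", length(x$hrv_snps),
              paste(x$hrv_snps, collapse = ", ")))
  invisible(x)
}
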