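## Synthetic cohort generator: genotypes with configurable LD, daily exposure
## series, panel outcomes from a random-intercept model with planted
## gene-environment interactions, and non-random loss to follow-up.

#' Simulate additive-coded genotypes
#'
#' Non-block SNPs are generated as two independent allele draws at the
#' specified MAF (so Hardy-Weinberg equilibrium holds in expectation) unless
#' flagged `hwe_violation`, in which case genotype probabilities follow the
#' inbreeding model `(q^2 + f p q, 2 p q (1 - f), p^2 + f p q)`. Block SNPs
#' are generated jointly by drawing two haplotypes per subject from the
#' block's haplotype frequencies.
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param snps List of [snp_spec()].
#' @param blocks List of [ld_block_spec()]; members must appear in `snps`
#'   and the marginal allele frequencies implied by the haplotype
#'   frequencies must match the members' MAFs (tolerance 1e-9).
#' @param seed Integer seed; fixed seed gives bit-identical output.
#' @return A `genotype_table`: list with `genotypes` (subjects x SNPs integer
#'   matrix of minor-allele counts) and `snp_info`
#'   (`data.frame(snp_id, gene, maf)` of specified values).
#' @export
simulate_genotypes <- function(n_subjects, snps, blocks = list(), seed = 1L) {
  stopifnot(n_subjects >= 1)
  ids <- vapply(snps, `[[`, "", "snp_id")
  if (anyDuplicated(ids)) stop_cfg("duplicate snp_id in panel")
  spec_by_id <- setNames(snps, ids)
  block_members <- unlist(lapply(blocks, `[[`, "snp_ids"))
  if (anyDuplicated(block_members))
    stop_cfg("SNP %s appears in more than one block",
             block_members[duplicated(block_members)][1])
  for (b in blocks) {
    for (j in seq_along(b$snp_ids)) {
      id <- b$snp_ids[j]
      if (!id %in% ids) stop_cfg("block references unknown snp_id %s", id)
      implied <- block_marginal_maf(b, j)
      if (abs(implied - spec_by_id[[id]]$maf) > 1e-9)
        stop_cfg("haplotype_freqs imply maf %.6f for %s but spec says %.6f",
                 implied, id, spec_by_id[[id]]$maf)
    }
  }
  geno <- with_seed(seed, {
    g <- matrix(NA_integer_, n_subjects, length(ids),
                dimnames = list(sprintf("S%04d", seq_len(n_subjects)), ids))
    loose <- setdiff(ids, block_members)
    for (id in loose) {
      s <- spec_by_id[[id]]
      if (s$hwe_violation) {
        p <- s$maf; q <- 1 - p; f <- s$f
        pr <- c(q^2 + f * p * q, 2 * p * q * (1 - f), p^2 + f * p * q)
        g[, id] <- sample(0:2, n_subjects, replace = TRUE, prob = pr)
      } else {
        g[, id] <- rbinom(n_subjects, 2L, s$maf)
      }
    }
    for (b in blocks) {
      labs <- names(b$haplotype_freqs)
      h1 <- sample(labs, n_subjects, replace = TRUE, prob = b$haplotype_freqs)
      h2 <- sample(labs, n_subjects, replace = TRUE, prob = b$haplotype_freqs)
      for (j in seq_along(b$snp_ids)) {
        g[, b$snp_ids[j]] <-
          (substr(h1, j, j) == "1") + (substr(h2, j, j) == "1")
      }
    }
    g
  })
  snp_info <- data.frame(
    snp_id = ids,
    gene = vapply(snps, `[[`, "", "gene"),
    maf = vapply(snps, `[[`, 0, "maf"),
    stringsAsFactors = FALSE, row.names = NULL)
  structure(list(genotypes = geno, snp_info = snp_info),
            class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat(sprintf("genotype_table: %d subjects x %d SNPs in %d genes\n",
              nrow(x$genotypes), ncol(x$genotypes),
              length(unique(x$snp_info$gene))))
  invisible(x)
}

default_pollutant_params <- function() {
  ## marginal mean/SD on the survey-day scale; ar = day-to-day autocorrelation
  list(pm10 = list(mean = 42.6, sd = 24.7, ar = 0.5),
       no2  = list(mean = 36.5, sd = 12.6, ar = 0.6),
       so2  = list(mean = 4.0,  sd = 2.1,  ar = 0.6))
}

default_met_params <- function() {
  ## annual sinusoid (peak end of July) plus day-to-day noise
  list(mean_temp = list(mean = 16.9, amplitude = 12, sd = 3.5),
       dew_point = list(mean = 6.2, amplitude = 14, sd = 4))
}

#' Simulate a daily exposure and meteorology series
#'
#' Pollutants follow stationary AR(1) processes with the given marginal mean,
#' SD and lag-1 autocorrelation, floored at a small positive value (0.1 unit)
#' so IQR scaling stays well-defined. Temperature and dew point follow an
#' annual sinusoid (peak day-of-year 212) plus AR-free daily noise.
#'
#' @param n_days Length of the series (>= 4, so lags up to 3 exist).
#' @param start_date First day (`Date`).
#' @param pollutant_params Named list per pollutant: `mean`, `sd`, `ar`.
#' @param met_params Named list for `mean_temp`/`dew_point`: `mean`,
#'   `amplitude`, `sd`.
#' @param seed Integer seed.
#' @return `data.frame(date, pm10, no2, so2, mean_temp, dew_point)` with
#'   strictly increasing daily dates.
#' @export
simulate_exposure_series <- function(n_days,
                                     start_date = as.Date("2008-08-01"),
                                     pollutant_params = default_pollutant_params(),
                                     met_params = default_met_params(),
                                     seed = 1L) {
  stopifnot(n_days >= 4)
  for (p in pollutant_params)
    if (p$sd < 0) stop_cfg("pollutant sd must be >= 0")
  for (m in met_params)
    if (m$sd < 0) stop_cfg("meteorology sd must be >= 0")
  dates <- start_date + seq_len(n_days) - 1L
  with_seed(seed, {
    ar1 <- function(n, sd, ar) {
      if (sd == 0) return(rep(0, n))
      z <- numeric(n)
      z[1] <- rnorm(1, 0, sd)
      if (n > 1) for (t in 2:n)
        z[t] <- ar * z[t - 1] + rnorm(1, 0, sd * sqrt(1 - ar^2))
      z
    }
    poll <- lapply(pollutant_params, function(p)
      pmax(p$mean + ar1(n_days, p$sd, p$ar), 0.1))
    doy <- as.integer(format(dates, "%j"))
    season <- cos(2 * pi * (doy - 212) / 365.25)
    met <- lapply(met_params, function(m)
      m$mean + m$amplitude * season + rnorm(n_days, 0, m$sd))
    data.frame(date = dates,
               pm10 = poll$pm10, no2 = poll$no2, so2 = poll$so2,
               mean_temp = met$mean_temp, dew_point = met$dew_point)
  })
}

#' Simulate a planned visit schedule
#'
#' Planned visits are evenly spaced over the study span with independent
#' uniform day jitter per subject-visit, mirroring a rolling panel with up
#' to 5 surveys over about two years.
#'
#' @param n_subjects Number of subjects.
#' @param n_visits Planned visits per subject.
#' @param start_date First possible visit date.
#' @param span_days Length of the visit window in days.
#' @param jitter_days Half-width of the uniform jitter (days).
#' @param seed Integer seed.
#' @return `data.frame(subject_id, visit, date)`.
#' @export
simulate_visit_schedule <- function(n_subjects, n_visits = 5,
                                    start_date = as.Date("2008-08-20"),
                                    span_days = 700, jitter_days = 14,
                                    seed = 1L) {
  base <- round(seq(0, span_days, length.out = n_visits))
  with_seed(seed, {
    jit <- matrix(sample(seq(-jitter_days, jitter_days), n_subjects * n_visits,
                         replace = TRUE), n_subjects, n_visits)
    data.frame(
      subject_id = rep(sprintf("S%04d", seq_len(n_subjects)), each = n_visits),
      visit = rep(seq_len(n_visits), n_subjects),
      date = start_date + as.vector(t(sweep(jit, 2, base, `+`))))
  })
}

#' Simulate baseline covariates with the study's marginal distributions
#'
#' Marginals follow the cohort's enrollment table: mean age 70.7 (SD 5.2,
#' floored at 60), 73.9 percent women, smoking status (5.5 / 6.6 / 85.4 /
#' 2.6 percent current / ex / non / no answer), alcohol (21.6 / 75.3 / 3.1
#' percent current / non / no answer), BMI mean 24.7. Covariates are drawn
#' independently; hypertension medication (35 percent) and years of
#' schooling are not tabulated in the source and use plausible values for an
#' elderly urban panel.
#'
#' @param n_subjects Number of subjects.
#' @param seed Integer seed.
#' @return `data.frame` with one row per subject.
#' @export
simulate_covariates <- function(n_subjects, seed = 1L) {
  with_seed(seed, {
    data.frame(
      subject_id = sprintf("S%04d", seq_len(n_subjects)),
      age = pmax(60, round(rnorm(n_subjects, 70.7, 5.2), 1)),
      sex = factor(ifelse(runif(n_subjects) < 0.739, "female", "male"),
                   levels = c("female", "male")),
      smoking = factor(sample(c("non-smoker", "current-smoker", "ex-smoker",
                                "did-not-answer"), n_subjects, replace = TRUE,
                              prob = c(0.854, 0.055, 0.066, 0.026)),
                       levels = c("non-smoker", "current-smoker", "ex-smoker",
                                  "did-not-answer")),
      alcohol = factor(sample(c("non-drinker", "current-drinker",
                                "did-not-answer"), n_subjects, replace = TRUE,
                              prob = c(0.753, 0.216, 0.031)),
                       levels = c("non-drinker", "current-drinker",
                                  "did-not-answer")),
      bmi = round(rnorm(n_subjects, 24.7, 3.0), 1),
      htn_med = rbinom(n_subjects, 1L, 0.35),
      schooling_years = sample(0:16, n_subjects, replace = TRUE,
                               prob = dnorm(0:16, 6, 4)),
      stringsAsFactors = FALSE)
  })
}

#' Default generating models for the six outcomes
#'
#' Intercepts and main pollutant effects (per IQR, PM10, lag 0) match the
#' cohort's published descriptive and main-model values; HRV outcomes are
#' generated on the natural-log scale with variance components matching the
#' reported geometric SDs. All interaction effects default to zero.
#'
#' @return Named list of [effect_spec()], one per outcome.
#' @export
default_effect_specs <- function() {
  list(
    sbp = effect_spec("sbp", "pm10", intercept = 131.8, main_effect = 0.93,
                      covariate_effects = c(age = 0.2, bmi = 0.4),
                      random_intercept_sd = 12, residual_sd = 10),
    dbp = effect_spec("dbp", "pm10", intercept = 74.5, main_effect = 0.62,
                      covariate_effects = c(age = 0.05, bmi = 0.3),
                      random_intercept_sd = 7, residual_sd = 6),
    sdnn = effect_spec("sdnn", "pm10", intercept = log(26.9),
                       main_effect = -0.01,
                       covariate_effects = c(age = -0.01),
                       random_intercept_sd = 0.38, residual_sd = 0.37),
    rmssd = effect_spec("rmssd", "pm10", intercept = log(20.5),
                        main_effect = -0.01,
                        covariate_effects = c(age = -0.01),
                        random_intercept_sd = 0.49, residual_sd = 0.49),
    lf = effect_spec("lf", "pm10", intercept = log(90.83),
                     main_effect = 0.004,
                     random_intercept_sd = 0.89, residual_sd = 0.88),
    hf = effect_spec("hf", "pm10", intercept = log(66.9),
                     main_effect = -0.03,
                     random_intercept_sd = 0.94, residual_sd = 0.94))
}

hrv_outcomes <- c("sdnn", "rmssd", "lf", "hf")

## Risk-allele count for one subject row over a planted SNP set.
risk_allele_count <- function(geno_matrix, interacting_snps) {
  if (is.null(interacting_snps) || nrow(interacting_snps) == 0)
    return(rep(0, nrow(geno_matrix)))
  tot <- rep(0, nrow(geno_matrix))
  for (i in seq_len(nrow(interacting_snps))) {
    g <- geno_matrix[, interacting_snps$snp_id[i]]
    if (interacting_snps$orientation[i] == "major_is_risk") g <- 2 - g
    tot <- tot + g
  }
  tot
}

#' Simulate panel outcomes from a random-intercept generating model
#'
#' For each outcome, `y_ij = intercept + covariate effects + beta_main x_ij +
#' beta_int G_i x_ij + b_i + s_i x_ij + e_ij` where `x_ij` is the pollutant
#' at the spec's true lag scaled to its IQR over the scheduled visit days and
#' `G_i` the subject's planted risk-allele count. HRV outcomes are generated
#' on the log scale and stored as positive raw values (to be log-transformed
#' by the analysis, as in the real data). Each subject's two BP readings are
#' represented directly by their mean.
#'
#' @param genotypes A `genotype_table` from [simulate_genotypes()].
#' @param exposures Daily series from [simulate_exposure_series()]; must
#'   cover every visit date minus the maximum true lag.
#' @param visit_schedule From [simulate_visit_schedule()].
#' @param effects Named list of [effect_spec()] (default
#'   [default_effect_specs()]); exactly one per generated outcome.
#' @param covariates Optional covariate table from [simulate_covariates()];
#'   generated internally when `NULL`.
#' @param seed Integer seed.
#' @return Long-format `data.frame` (one row per subject-visit) with outcome,
#'   covariate and date columns.
#' @export
simulate_panel_outcomes <- function(genotypes, exposures, visit_schedule,
                                    effects = default_effect_specs(),
                                    covariates = NULL, seed = 1L) {
  outs <- vapply(effects, `[[`, "", "outcome")
  if (anyDuplicated(outs)) stop_cfg("more than one effect_spec for outcome %s",
                                    outs[duplicated(outs)][1])
  names(effects) <- outs
  max_lag <- max(vapply(effects, `[[`, 0, "true_lag"))
  bad <- !(visit_schedule$date - max_lag) %in% exposures$date |
    !visit_schedule$date %in% exposures$date
  if (any(bad))
    stop_cfg("visit date %s outside exposure coverage (max lag %d)",
             as.character(visit_schedule$date[bad][1]), max_lag)
  if (is.null(covariates))
    covariates <- simulate_covariates(nrow(genotypes$genotypes),
                                      derive_seed(seed, "covariates"))
  panel <- merge(visit_schedule, covariates, by = "subject_id", sort = FALSE)
  panel <- panel[order(panel$subject_id, panel$visit), , drop = FALSE]
  rownames(panel) <- NULL
  n <- nrow(panel)
  subj <- rownames(genotypes$genotypes)
  with_seed(derive_seed(seed, "outcomes"), {
    ## visit-level BMI wobble around baseline
    panel$bmi <- panel$bmi + round(rnorm(n, 0, 0.5), 1)
    panel$sex_male <- as.integer(panel$sex == "male")
    for (ef in effects) {
      lagged_dates <- panel$date - ef$true_lag
      x_raw <- exposures[[ef$pollutant]][match(lagged_dates, exposures$date)]
      iqr <- diff(quantile7(x_raw[!duplicated(lagged_dates)], c(.25, .75)))
      x <- x_raw / iqr
      G <- risk_allele_count(genotypes$genotypes, ef$interacting_snps)
      names(G) <- subj
      re_b <- rnorm(length(subj), 0, ef$random_intercept_sd)
      re_s <- if (ef$random_slope_sd > 0) {
        ef$random_slope_sd * (ef$slope_intercept_cor *
                                re_b / max(ef$random_intercept_sd, 1e-12) +
                              sqrt(1 - ef$slope_intercept_cor^2) *
                                rnorm(length(subj)))
      } else rep(0, length(subj))
      names(re_b) <- names(re_s) <- subj
      lp <- ef$intercept + ef$main_effect * x +
        ef$interaction_per_risk_allele * G[panel$subject_id] * x +
        re_b[panel$subject_id] + re_s[panel$subject_id] * x +
        rnorm(n, 0, ef$residual_sd)
      if (!is.null(ef$covariate_effects)) {
        for (cv in names(ef$covariate_effects)) {
          if (!cv %in% names(panel) || !is.numeric(panel[[cv]]))
            stop_cfg("covariate_effects names a missing/non-numeric column: %s", cv)
          lp <- lp + ef$covariate_effects[[cv]] * panel[[cv]]
        }
      }
      panel[[ef$outcome]] <-
        if (ef$outcome %in% hrv_outcomes) exp(lp) else lp
    }
    ## keep pulse pressure positive in the rare tail where the two
    ## independently generated BP series cross
    if (all(c("sbp", "dbp") %in% names(panel)))
      panel$sbp <- pmax(panel$sbp, panel$dbp + 1)
    panel$sex_male <- NULL
    panel
  })
}

#' Apply (possibly non-random) loss to follow-up
#'
#' The first visit is always retained. Each later visit is retained with
#' probability `expit(linear predictor)` evaluated on the previous visit's
#' row (any panel column, including outcomes like `sbp`, may appear in the
#' coefficients). Dropout is monotone: once a visit is missed all later
#' visits are missed.
#'
#' @param panel Long panel from [simulate_panel_outcomes()].
#' @param spec A [dropout_spec()].
#' @param seed Integer seed.
#' @return The panel with dropped rows removed.
#' @export
apply_dropout <- function(panel, spec, seed = 1L) {
  if (spec$mechanism == "none") return(panel)
  coefs <- spec$logit_coefficients
  covs <- setdiff(names(coefs), "intercept")
  miss <- setdiff(covs, names(panel))
  if (length(miss)) stop_cfg("dropout coefficient names missing column: %s",
                             miss[1])
  with_seed(seed, {
    keep <- rep(TRUE, nrow(panel))
    for (id in unique(panel$subject_id)) {
      rows <- which(panel$subject_id == id)
      rows <- rows[order(panel$visit[rows])]
      for (k in seq_along(rows)[-1]) {
        prev <- rows[k - 1]
        eta <- coefs[["intercept"]] %||% 0
        for (cv in covs) eta <- eta + coefs[[cv]] * panel[[cv]][prev]
        if (runif(1) > expit(eta)) {
          keep[rows[k:length(rows)]] <- FALSE
          break
        }
      }
    }
    panel[keep, , drop = FALSE]
  })
}

#' Simulate a complete synthetic study
#'
#' Assembles the default scenario: the 47-SNP panel with four LD blocks and
#' one planted Hardy-Weinberg violation, a daily exposure series covering the
#' visit window plus lags, 5 planned visits per subject over roughly two
#' years, outcomes from [default_effect_specs()] (or a caller-supplied list),
#' and optional dropout.
#'
#' @param n_subjects Number of subjects (study default 547).
#' @param seed Master integer seed; module streams are derived from it.
#' @param effects Named list of [effect_spec()].
#' @param dropout A [dropout_spec()].
#' @param snps,blocks Genotype panel specification.
#' @param n_visits Planned visits per subject.
#' @return List with `panel`, `genotypes`, `exposures`, `schedule`.
#' @export
simulate_study <- function(n_subjects = 547, seed = 1L,
                           effects = default_effect_specs(),
                           dropout = dropout_spec("none"),
                           snps = default_snp_panel(),
                           blocks = default_ld_blocks(snps),
                           n_visits = 5) {
  genotypes <- simulate_genotypes(n_subjects, snps, blocks,
                                  derive_seed(seed, "genotypes"))
  exposures <- simulate_exposure_series(740,
                                        start_date = as.Date("2008-08-01"),
                                        seed = derive_seed(seed, "exposures"))
  schedule <- simulate_visit_schedule(n_subjects, n_visits = n_visits,
                                      seed = derive_seed(seed, "schedule"))
  panel <- simulate_panel_outcomes(genotypes, exposures, schedule,
                                   effects = effects,
                                   seed = derive_seed(seed, "panel"))
  panel <- apply_dropout(panel, dropout, derive_seed(seed, "dropout"))
  list(panel = panel, genotypes = genotypes, exposures = exposures,
       schedule = schedule)
}
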