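## Inverse-probability-of-follow-up weighting: model the probability that a
## planned follow-up visit was observed from prior-visit covariates, weight
## observed follow-ups by the inverse probability, refit the mixed models.

#' Fit the follow-up (retention) logistic model
#'
#' For every planned visit `v >= 2` whose previous visit was observed, the
#' binary outcome "visit v observed" is regressed on the prior visit's
#' covariates: age, sex, BMI, years of schooling, systolic blood pressure,
#' season (calendar quarter of the prior visit) and outdoor (daily mean)
#' temperature on the prior visit day.
#'
#' @param panel Observed long panel (monotone dropout assumed).
#' @param exposures Daily exposure series supplying `mean_temp`; if `NULL`
#'   the temperature term is omitted.
#' @param n_planned Number of planned visits (default: max observed visit).
#' @param covariates Prior-visit covariate terms; `"season"` and
#'   `"prior_temp"` are derived, the rest must be panel columns.
#' @return A `followup_model`: list with `model` (the glm), `atrisk`
#'   (`data.frame(subject_id, visit, observed, p_hat)`) and `covariates`.
#' @export
fit_followup_model <- function(panel, exposures = NULL,
                               n_planned = max(panel$visit),
                               covariates = c("age", "sex", "bmi",
                                              "schooling_years", "sbp",
                                              "season", "prior_temp")) {
  if (n_planned < 2) stop_cfg("need >= 2 planned visits")
  if (is.null(exposures)) covariates <- setdiff(covariates, "prior_temp")
  plain <- setdiff(covariates, c("season", "prior_temp"))
  miss <- setdiff(plain, names(panel))
  if (length(miss)) stop_cfg("panel lacks follow-up covariate: %s", miss[1])
  rows <- list()
  for (id in unique(panel$subject_id)) {
    sub <- panel[panel$subject_id == id, , drop = FALSE]
    sub <- sub[order(sub$visit), , drop = FALSE]
    for (v in 2:n_planned) {
      prev <- which(sub$visit == v - 1)
      if (!length(prev)) next      # prior visit missed -> not at risk
      r <- sub[prev, plain, drop = FALSE]
      r$subject_id <- id
      r$visit <- v
      r$observed <- as.integer(v %in% sub$visit)
      r$prior_date <- sub$date[prev]
      rows[[length(rows) + 1]] <- r
    }
  }
  atrisk <- do.call(rbind, rows)
  rownames(atrisk) <- NULL
  if ("season" %in% covariates)
    atrisk$season <- droplevels(factor(quarters(atrisk$prior_date),
                                       levels = c("Q1", "Q2", "Q3", "Q4")))
  if ("season" %in% covariates && nlevels(atrisk$season) < 2) {
    message("single season among prior visits; season term dropped")
    covariates <- setdiff(covariates, "season")
  }
  if ("prior_temp" %in% covariates)
    atrisk$prior_temp <- exposures$mean_temp[match(atrisk$prior_date,
                                                   exposures$date)]
  n_inc <- sum(!complete.cases(atrisk[, covariates, drop = FALSE]))
  if (n_inc) message(sprintf("%d at-risk rows dropped (missing covariates)",
                             n_inc))
  if (length(unique(atrisk$observed)) < 2)
    stop_cfg("follow-up outcome is degenerate (all visits %s)",
             if (all(atrisk$observed == 1)) "observed" else "missed")
  fml <- as.formula(paste("observed ~", paste(covariates, collapse = " + ")))
  sep_warn <- FALSE
  fit <- withCallingHandlers(
    glm(fml, family = binomial(), data = atrisk),
    warning = function(w) {
      if (grepl("numerically 0 or 1", conditionMessage(w))) {
        sep_warn <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  if (sep_warn)
    stop_cfg(paste("separation in the follow-up model (fitted probabilities",
                   "0/1); consider penalized logistic regression or a",
                   "reduced covariate set"))
  atrisk$p_hat <- predict(fit, newdata = atrisk, type = "response")
  structure(list(model = fit,
                 atrisk = atrisk[, c("subject_id", "visit", "observed",
                                     "p_hat")],
                 covariates = covariates),
            class = "followup_model")
}

#' @export
print.followup_model <- function(x, ...) {
  cat(sprintf("Follow-up logistic model: %d at-risk visit slots, %.1f%% observed\n",
              nrow(x$atrisk), 100 * mean(x$atrisk$observed)))
  print(coef(x$model), digits = 3)
  invisible(x)
}

#' Inverse-probability-of-follow-up weights
#'
#' Every subject's first observation gets weight 1; each observed follow-up
#' gets `1 / p_hat` with `p_hat` clipped below at `clip_floor` so weights
#' stay bounded.
#'
#' @param panel Observed long panel.
#' @param model A `followup_model`.
#' @param clip_floor Lower clip for the predicted probability (default
#'   0.01, i.e. weights at most 100).
#' @return `data.frame(subject_id, visit, p_hat, weight, clipped,
#'   first_visit)` aligned to `panel` rows.
#' @export
compute_ipw_weights <- function(panel, model, clip_floor = 0.01) {
  first <- aggregate(visit ~ subject_id, panel, min)
  is_first <- panel$visit == first$visit[match(panel$subject_id,
                                               first$subject_id)]
  key <- function(id, v) paste(id, v, sep = "\r")
  m <- match(key(panel$subject_id, panel$visit),
             key(model$atrisk$subject_id, model$atrisk$visit))
  p <- model$atrisk$p_hat[m]
  if (any(!is_first & is.na(p)))
    stop_cfg("no follow-up probability for an observed follow-up row")
  clipped <- !is_first & !is.na(p) & p < clip_floor
  if (any(clipped))
    message(sprintf("%d probabilities clipped at %.3g", sum(clipped),
                    clip_floor))
  p_cl <- pmax(p, clip_floor)
  w <- ifelse(is_first, 1, 1 / p_cl)
  data.frame(subject_id = panel$subject_id, visit = panel$visit,
             p_hat = ifelse(is_first, NA_real_, p),
             weight = w, clipped = clipped, first_visit = is_first,
             stringsAsFactors = FALSE)
}

#' Refit a model with inverse-probability-of-follow-up weights
#'
#' The weights enter the mixed-model likelihood as observation
#' (frequency-type) weights — an approximation to weighted GEE documented
#' with the method.
#'
#' @param panel Analysis panel.
#' @param weights `data.frame` from [compute_ipw_weights()] (matched to
#'   panel rows by subject and visit).
#' @param spec A [model_spec()] with `lag` set.
#' @return A `gxe_fit`.
#' @export
weighted_refit <- function(panel, weights, spec) {
  key <- function(id, v) paste(id, v, sep = "\r")
  m <- match(key(panel$subject_id, panel$visit),
             key(weights$subject_id, weights$visit))
  if (anyNA(m)) stop_cfg("weights do not cover every panel row")
  fit_main_model(panel, spec, weights = weights$weight[m])
}
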