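## Genetic risk scores over the pruned interaction-positive SNP panels,
## tertile stratification, stratified effect estimation, heterogeneity
## testing, and the cohort exclusion filter.

#' Apply the cohort exclusion filter
#'
#' Subjects with no blood-pressure measurement are removed first, then
#' subjects (of the remainder) with no heart-rate-variability information.
#'
#' @param roster `data.frame` with `subject_id` and logical `has_bp`,
#'   `has_hrv` availability flags.
#' @return List with `roster` (filtered) and `report`
#'   (`n_enrolled`, `exclusions` data.frame of reason/count, `n_analyzed`).
#' @export
apply_exclusions <- function(roster) {
  stopifnot(all(c("subject_id", "has_bp", "has_hrv") %in% names(roster)))
  n0 <- nrow(roster)
  no_bp <- sum(!roster$has_bp)
  r1 <- roster[roster$has_bp, , drop = FALSE]
  no_hrv <- sum(!r1$has_hrv)
  r2 <- r1[r1$has_hrv, , drop = FALSE]
  if (nrow(r2) == 0) warning("no subjects remain after exclusions")
  report <- list(
    n_enrolled = n0,
    exclusions = data.frame(
      reason = c("no blood pressure measurement",
                 "no heart rate variability information"),
      count = c(no_bp, no_hrv), stringsAsFactors = FALSE),
    n_analyzed = nrow(r2))
  list(roster = r2, report = report)
}

#' Risk-allele orientations inherited from a screen
#'
#' For each SNP in an outcome family's candidate set, the orientation of its
#' single smallest-p interaction within the family (ties: first row).
#'
#' @param screen A `gxe_screen`.
#' @param family `"blood_pressure"` or `"heart_rate_variability"`.
#' @return `data.frame(snp_id, orientation)`.
#' @export
screen_orientations <- function(screen,
                                family = c("blood_pressure",
                                           "heart_rate_variability")) {
  family <- match.arg(family)
  fam_outcomes <- if (family == "blood_pressure") screen$bp_outcomes
                  else screen$hrv_outcomes
  snps <- if (family == "blood_pressure") screen$bp_snps else screen$hrv_snps
  sub <- screen$results[screen$results$outcome %in% fam_outcomes &
                          !screen$results$skipped, ]
  ori <- vapply(snps, function(id) {
    rows <- sub[sub$snp_id == id, ]
    rows$orientation[which.min(rows$p_interaction)]
  }, "")
  data.frame(snp_id = snps, orientation = unname(ori),
             stringsAsFactors = FALSE)
}

#' Compute unweighted genetic risk scores
#'
#' Sum of risk alleles over the panel: the genotype if the minor allele is
#' the risk allele, `2 - genotype` otherwise. Subjects missing any panel
#' genotype get `NA` by default (complete-case); `impute = "mean"`
#' substitutes the per-SNP mean risk count.
#'
#' @param genotypes A `genotype_table`.
#' @param panel `data.frame(snp_id, orientation)` of the pruned panel.
#' @param impute `"none"` (default) or `"mean"`.
#' @return A `grs` object: `score` (named per-subject), `panel`, `k`.
#' @export
compute_grs <- function(genotypes, panel, impute = c("none", "mean")) {
  impute <- match.arg(impute)
  if (nrow(panel) == 0) stop_cfg("empty SNP panel")
  miss <- setdiff(panel$snp_id, colnames(genotypes$genotypes))
  if (length(miss)) stop_cfg("panel SNP %s not in genotype table", miss[1])
  g <- genotypes$genotypes[, panel$snp_id, drop = FALSE]
  for (i in seq_len(nrow(panel)))
    if (panel$orientation[i] == "major_is_risk") g[, i] <- 2 - g[, i]
  if (impute == "mean" && anyNA(g))
    for (j in seq_len(ncol(g)))
      g[is.na(g[, j]), j] <- mean(g[, j], na.rm = TRUE)
  score <- rowSums(g)
  structure(list(score = score, panel = panel, k = nrow(panel)),
            class = "grs")
}

#' @export
print.grs <- function(x, ...) {
  cat(sprintf("Genetic risk score over %d SNPs; range %s-%s (possible 0-%d)\n",
              x$k, min(x$score, na.rm = TRUE), max(x$score, na.rm = TRUE),
              2 * x$k))
  invisible(x)
}

#' Assign risk-score tertiles
#'
#' Cutpoints are the empirical 1/3 and 2/3 quantiles of the integer scores
#' (inverse-ECDF, "type 1", so cutpoints are attained score values); ties at
#' a cutpoint go to the lower group, which yields contiguous integer bands.
#'
#' @param scores Integer scores (named by subject; `NA` allowed and left
#'   unassigned).
#' @return List with `cutpoints` (c(q1, q2)), `tertile` (factor
#'   low/moderate/high aligned to `scores`), and `bands` (score range per
#'   group, e.g. `"12-13"`).
#' @export
assign_tertiles <- function(scores) {
  s <- scores[!is.na(scores)]
  if (length(unique(s)) < 3) stop_cfg("need >= 3 distinct scores for tertiles")
  q <- unname(quantile(s, c(1 / 3, 2 / 3), type = 1, names = FALSE))
  tert <- rep(NA_character_, length(scores))
  tert[!is.na(scores) & scores <= q[1]] <- "low"
  tert[!is.na(scores) & scores > q[1] & scores <= q[2]] <- "moderate"
  tert[!is.na(scores) & scores > q[2]] <- "high"
  tert <- factor(tert, levels = c("low", "moderate", "high"))
  names(tert) <- names(scores)
  band <- function(g) {
    v <- scores[!is.na(tert) & tert == g]
    if (!length(v)) return(NA_character_)
    sprintf("%d-%d", min(v), max(v))
  }
  list(cutpoints = q, tertile = tert,
       bands = c(low = band("low"), moderate = band("moderate"),
                 high = band("high")))
}

#' Tertile-stratified pollutant effect estimates
#'
#' Fits the main model separately within each tertile. The IQR used for
#' scaling is computed on the full (unstratified) panel so per-IQR effects
#' are comparable across strata.
#'
#' @param panel Analysis panel.
#' @param tertile Factor from [assign_tertiles()], named by subject id.
#' @param spec A [model_spec()] with `lag` set.
#' @return `data.frame` with one row per tertile (estimate per IQR, SE, CI,
#'   n_obs, convergence flag).
#' @export
stratified_association <- function(panel, tertile, spec) {
  pd <- prep_fit_data(panel, spec)
  full_iqr <- pd$iqr
  out <- lapply(levels(tertile), function(g) {
    ids <- names(tertile)[!is.na(tertile) & tertile == g]
    sub <- panel[panel$subject_id %in% ids, , drop = FALSE]
    f <- tryCatch(fit_main_model(sub, spec, iqr = full_iqr),
                  error = function(e) NULL)
    if (is.null(f))
      data.frame(tertile = g, pollutant = spec$pollutant,
                 outcome = spec$outcome, estimate = NA_real_, se = NA_real_,
                 ci_low = NA_real_, ci_high = NA_real_, n_obs = nrow(sub),
                 converged = FALSE, stringsAsFactors = FALSE)
    else
      data.frame(tertile = g, pollutant = spec$pollutant,
                 outcome = spec$outcome, estimate = f$estimate, se = f$se,
                 ci_low = f$ci[1], ci_high = f$ci[2], n_obs = f$n_obs,
                 converged = TRUE, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Heterogeneity test across risk-score tertiles
#'
#' Adds the ordinal tertile score (0/1/2) and its product with the
#' IQR-scaled pollutant to the main model; the Wald p-value of the product
#' term tests heterogeneity of the pollutant effect across tertiles. A 2-df
#' categorical version (`ordinal = FALSE`) treats the tertile as a factor
#' and tests both products by LRT.
#'
#' @param panel Analysis panel.
#' @param tertile Factor from [assign_tertiles()], named by subject id.
#' @param spec A [model_spec()] with `lag` set.
#' @param ordinal Use the ordinal 0/1/2 product term (default `TRUE`).
#' @return List with `p_heterogeneity`, `estimate` (product-term slope, for
#'   the ordinal version), `pollutant`, `outcome`.
#' @export
heterogeneity_test <- function(panel, tertile, spec, ordinal = TRUE) {
  tscore <- setNames(as.integer(tertile) - 1L, names(tertile))
  panel$tert_score <- tscore[panel$subject_id]
  pd <- prep_fit_data(panel, spec, extra_cols = "tert_score")
  covs <- c(spec$covariates, pd$atemp_col)
  if (ordinal) {
    m <- fit_lmm(pd$data, spec$outcome,
                 c(covs, "poll_iqr", "tert_score", "poll_iqr:tert_score"))
    tab <- fe_table(m)
    row <- tab[tab$term == "poll_iqr:tert_score", ]
    list(p_heterogeneity = row$p, estimate = row$estimate,
         pollutant = spec$pollutant, outcome = spec$outcome)
  } else {
    pd$data$tert_f <- factor(pd$data$tert_score)
    full <- fit_lmm(pd$data, spec$outcome,
                    c(covs, "poll_iqr", "tert_f", "poll_iqr:tert_f"))
    nested <- fit_lmm(pd$data, spec$outcome, c(covs, "poll_iqr", "tert_f"))
    lrt <- max(0, 2 * (as.numeric(logLik(full)) - as.numeric(logLik(nested))))
    list(p_heterogeneity = pchisq(lrt, 2, lower.tail = FALSE),
         estimate = NA_real_, pollutant = spec$pollutant,
         outcome = spec$outcome)
  }
}

#' Alternative risk-score panel from the other LD-block members
#'
#' Rebuilds the pruned panel choosing, in every multi-SNP block, a member
#' different from the primary choice — the robustness check that risk-score
#' conclusions do not hinge on which block representative was kept.
#'
#' @param candidates Interaction-positive SNP ids.
#' @param blocks Blocks from [blocks_from_pairs()] / [find_ld_blocks()].
#' @param stat Optional named statistic used by the primary rule.
#' @return Character vector of SNP ids, same cardinality as the primary
#'   panel.
#' @export
alternative_panel <- function(candidates, blocks, stat = NULL) {
  prune_blocks(candidates, blocks, stat = stat, rule = "other_member")
}
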