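## Configuration, CSV I/O and end-to-end orchestration.

#' Default pipeline configuration
#'
#' Every default corresponds to a documented analysis choice: unadjusted
#' screening alpha 0.05, HWE exclusion alpha 0.001, |D'| block threshold
#' 0.8, lags 0-3, type-7 quantiles for IQRs, ML mixed models.
#'
#' @param ... Overrides (name = value).
#' @return Named list of configuration values.
#' @export
default_config <- function(...) {
  cfg <- list(
    n_subjects = 547, seed = 1L, n_visits = 5,
    pollutants = c("pm10", "no2", "so2"),
    bp_outcomes = c("sbp", "dbp", "map"),
    hrv_outcomes = c("log_sdnn", "log_rmssd", "log_lf", "log_hf"),
    alpha = 0.05, hwe_alpha = 0.001, ld_threshold = 0.8,
    max_lag = 3, run_joint = FALSE, run_ipw = FALSE,
    run_alternative_panel = FALSE,
    panel_csv = NULL, genotypes_csv = NULL, snp_info_csv = NULL,
    exposures_csv = NULL)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop_cfg("unknown config field: %s", unknown[1])
  cfg[names(over)] <- over
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys mirror [default_config()].
#' @return Validated configuration list.
#' @export
read_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop_cfg("reading YAML configs requires the yaml package")
  do.call(default_config, yaml::read_yaml(path))
}

#' @rdname io_csv
#' @export
write_exposure_csv <- function(series, path) {
  write.csv(series, path, row.names = FALSE)
  invisible(path)
}

#' CSV input/output for the pipeline's tabular artifacts
#'
#' Long-format panel (one row per subject-visit), daily exposure series
#' (date, pm10, no2, so2, mean_temp, dew_point), and genotype matrix
#' (subject_id plus one 0/1/2 column per SNP) with a SNP-metadata sidecar
#' (snp_id, gene, maf). Dates are ISO-8601.
#'
#' @param series,panel Data frames to write.
#' @param genotypes A `genotype_table`.
#' @param path,geno_path,info_path File paths.
#' @return The path (writers) or the object (readers).
#' @name io_csv
#' @export
read_exposure_csv <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  d$date <- as.Date(d$date)
  d
}

#' @rdname io_csv
#' @export
write_panel_csv <- function(panel, path) {
  write.csv(panel, path, row.names = FALSE)
  invisible(path)
}

#' @rdname io_csv
#' @export
read_panel_csv <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  d$date <- as.Date(d$date)
  for (v in c("sex", "smoking", "alcohol"))
    if (v %in% names(d)) d[[v]] <- factor(d[[v]])
  d
}

#' @rdname io_csv
#' @export
write_genotypes_csv <- function(genotypes, geno_path, info_path) {
  g <- data.frame(subject_id = rownames(genotypes$genotypes),
                  genotypes$genotypes, check.names = FALSE,
                  stringsAsFactors = FALSE)
  write.csv(g, geno_path, row.names = FALSE)
  write.csv(genotypes$snp_info, info_path, row.names = FALSE)
  invisible(geno_path)
}

#' @rdname io_csv
#' @export
read_genotypes_csv <- function(geno_path, info_path) {
  g <- read.csv(geno_path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(g[, setdiff(names(g), "subject_id"), drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- g$subject_id
  info <- read.csv(info_path, stringsAsFactors = FALSE)
  structure(list(genotypes = m, snp_info = info), class = "genotype_table")
}

#' Exposure summary over survey days
#'
#' Mean, SD, median, range and IQR for each exposure and meteorological
#' variable, restricted to the days on which health examinations were
#' conducted.
#'
#' @param series Daily exposure series.
#' @param dates Survey dates (duplicates collapse to distinct days).
#' @return `data.frame` with one row per variable.
#' @export
summarize_exposures <- function(series, dates) {
  days <- sort(unique(dates))
  if (length(days) < 4) stop_cfg("need >= 4 survey days")
  sub <- series[series$date %in% days, , drop = FALSE]
  vars <- setdiff(names(sub), "date")
  do.call(rbind, lapply(vars, function(v) {
    x <- sub[[v]]
    q <- quantile7(x, c(0.25, 0.75))
    data.frame(variable = v, mean = mean(x), sd = sd(x), median = median(x),
               min = min(x), max = max(x), iqr = q[2] - q[1],
               stringsAsFactors = FALSE)
  }))
}

#' Run the full analysis pipeline
#'
#' Sequence: load or simulate data, cohort exclusions, outcome derivation
#' and lag features, genotype QC (MAF, HWE exclusion), interaction
#' screening with AIC lag selection, within-gene LD blocks and one-per-block
#' pruning, genetic risk scores and tertiles per outcome family,
#' tertile-stratified estimates with heterogeneity tests, and optional
#' sensitivity analyses (2-df joint test, alternative panel, IPW refits of
#' the main models). Idempotent given config and seed.
#'
#' @param config List from [default_config()] or [read_config()].
#' @return A report bundle (list): `cohort`, `exposure_summary`, `qc`,
#'   `screen`, `blocks`, `grs`, `stratified`, `heterogeneity`,
#'   `main_effects`, optional `ipw`, plus the `data` used.
#' @export
run_pipeline <- function(config = default_config()) {
  cfg <- do.call(default_config, config)
  from_files <- !is.null(cfg$panel_csv)
  if (from_files) {
    panel <- read_panel_csv(cfg$panel_csv)
    genotypes <- read_genotypes_csv(cfg$genotypes_csv, cfg$snp_info_csv)
    exposures <- read_exposure_csv(cfg$exposures_csv)
  } else {
    sim <- simulate_study(n_subjects = cfg$n_subjects, seed = cfg$seed,
                          n_visits = cfg$n_visits)
    panel <- sim$panel; genotypes <- sim$genotypes
    exposures <- sim$exposures
  }
  ## cohort exclusions from outcome availability
  ids <- unique(panel$subject_id)
  has <- function(cols) vapply(ids, function(id) {
    sub <- panel[panel$subject_id == id, cols, drop = FALSE]
    any(stats::complete.cases(sub))
  }, TRUE)
  roster <- data.frame(subject_id = ids,
                       has_bp = has(c("sbp", "dbp")),
                       has_hrv = has(hrv_outcomes),
                       stringsAsFactors = FALSE)
  excl <- apply_exclusions(roster)
  panel <- panel[panel$subject_id %in% excl$roster$subject_id, , drop = FALSE]

  apanel <- prepare_analysis_panel(panel, exposures,
                                   pollutants = cfg$pollutants,
                                   max_lag = cfg$max_lag)
  exposure_summary <- summarize_exposures(exposures, panel$date)

  hwe <- apply_hwe_exclusion(genotypes, alpha = cfg$hwe_alpha)
  genotypes <- hwe$table

  screen <- screen_all(apanel, genotypes, pollutants = cfg$pollutants,
                       bp_outcomes = cfg$bp_outcomes,
                       hrv_outcomes = cfg$hrv_outcomes,
                       alpha = cfg$alpha, joint = cfg$run_joint)

  ld <- find_ld_blocks(genotypes, threshold = cfg$ld_threshold)

  main_effects <- do.call(rbind, lapply(cfg$pollutants, function(poll)
    do.call(rbind, lapply(c(cfg$bp_outcomes, cfg$hrv_outcomes),
                          function(out) {
      lag <- screen$lags[[paste(out, poll, sep = ".")]]
      f <- fit_main_model(apanel, model_spec(out, poll, lag = lag))
      data.frame(outcome = out, pollutant = poll, lag = lag,
                 n_obs = f$n_obs, estimate = f$estimate,
                 ci_low = f$ci[1], ci_high = f$ci[2], p = f$p,
                 stringsAsFactors = FALSE)
    }))))

  families <- list(blood_pressure = cfg$bp_outcomes,
                   heart_rate_variability = cfg$hrv_outcomes)
  grs_out <- list(); strat_out <- list(); het_out <- list()
  for (fam in names(families)) {
    cands <- if (fam == "blood_pressure") screen$bp_snps else screen$hrv_snps
    if (length(cands) < 2) next
    sub <- screen$results[screen$results$outcome %in% families[[fam]] &
                            !screen$results$skipped, ]
    best_p <- vapply(cands, function(id)
      min(sub$p_interaction[sub$snp_id == id], na.rm = TRUE), 0)
    pruned <- prune_blocks(cands, ld$blocks, stat = best_p)
    ori <- screen_orientations(screen, fam)
    grs <- compute_grs(genotypes,
                       ori[ori$snp_id %in% pruned, , drop = FALSE])
    tert <- assign_tertiles(grs$score)
    fam_res <- list(panel_snps = pruned, grs = grs, tertiles = tert)
    if (cfg$run_alternative_panel)
      fam_res$alternative_panel <- alternative_panel(cands, ld$blocks,
                                                     stat = best_p)
    grs_out[[fam]] <- fam_res
    for (out in families[[fam]]) {
      for (poll in cfg$pollutants) {
        lag <- screen$lags[[paste(out, poll, sep = ".")]]
        sp <- model_spec(out, poll, lag = lag)
        strat_out[[length(strat_out) + 1]] <-
          cbind(family = fam,
                stratified_association(apanel, tert$tertile, sp))
        het <- heterogeneity_test(apanel, tert$tertile, sp)
        het_out[[length(het_out) + 1]] <-
          data.frame(family = fam, outcome = out, pollutant = poll,
                     p_heterogeneity = het$p_heterogeneity,
                     stringsAsFactors = FALSE)
      }
    }
  }

  bundle <- list(cohort = excl$report, exposure_summary = exposure_summary,
                 qc = hwe$qc, hwe_excluded = hwe$excluded, screen = screen,
                 blocks = ld, main_effects = main_effects, grs = grs_out,
                 stratified = if (length(strat_out))
                   do.call(rbind, strat_out) else NULL,
                 heterogeneity = if (length(het_out))
                   do.call(rbind, het_out) else NULL,
                 config = cfg)
  if (cfg$run_ipw) {
    fum <- fit_followup_model(apanel, exposures,
                              n_planned = cfg$n_visits)
    w <- compute_ipw_weights(apanel, fum)
    bundle$ipw <- list(
      followup = fum, weights = w,
      refits = do.call(rbind, lapply(cfg$pollutants, function(poll) {
        out <- cfg$bp_outcomes[1]
        lag <- screen$lags[[paste(out, poll, sep = ".")]]
        f <- weighted_refit(apanel, w, model_spec(out, poll, lag = lag))
        data.frame(outcome = out, pollutant = poll, estimate = f$estimate,
                   ci_low = f$ci[1], ci_high = f$ci[2],
                   stringsAsFactors = FALSE)
      })))
  }
  bundle
}

#' Write the report bundle's tables as CSV files
#'
#' @param bundle Output of [run_pipeline()].
#' @param dir Output directory (created if absent).
#' @return The directory, invisibly.
#' @export
write_report_bundle <- function(bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wr <- function(x, name) if (!is.null(x))
    write.csv(x, file.path(dir, paste0(name, ".csv")), row.names = FALSE)
  wr(bundle$exposure_summary, "exposure_summary")
  wr(bundle$qc, "snp_qc")
  wr(bundle$screen$results, "interaction_screen")
  wr(bundle$blocks$pairs, "ld_pairs")
  wr(bundle$main_effects, "main_effects")
  wr(bundle$stratified, "stratified_estimates")
  wr(bundle$heterogeneity, "heterogeneity")
  cohort <- data.frame(
    quantity = c("n_enrolled", bundle$cohort$exclusions$reason,
                 "n_analyzed"),
    value = c(bundle$cohort$n_enrolled, bundle$cohort$exclusions$count,
              bundle$cohort$n_analyzed))
  wr(cohort, "cohort")
  for (fam in names(bundle$grs)) {
    g <- bundle$grs[[fam]]
    wr(data.frame(subject_id = names(g$grs$score), score = g$grs$score,
                  tertile = as.character(g$tertiles$tertile)),
       paste0("grs_", fam))
  }
  invisible(dir)
}
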