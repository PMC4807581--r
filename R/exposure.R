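## Exposure and outcome preprocessing: apparent temperature, lag features,
## IQR scaling, mean arterial pressure, BP averaging, log-HRV.

#' Apparent temperature
#'
#' Perceived temperature combining air temperature and humidity:
#' `-2.653 + 0.994 * T + 0.0153 * D^2` with `T` the daily mean temperature
#' and `D` the daily dew-point temperature, both in degrees Celsius.
#'
#' @param mean_temp Daily mean temperature (deg C).
#' @param dew_point Daily dew point (deg C).
#' @return Apparent temperature (deg C), vectorised.
#' @export
apparent_temperature <- function(mean_temp, dew_point) {
  assert_finite(mean_temp, "mean_temp")
  assert_finite(dew_point, "dew_point")
  -2.653 + 0.994 * mean_temp + 0.0153 * dew_point^2
}

#' Mean arterial pressure
#'
#' One-third systolic plus two-thirds diastolic pressure.
#'
#' @param sbp Systolic blood pressure (mmHg).
#' @param dbp Diastolic blood pressure (mmHg); must not exceed `sbp`.
#' @return MAP in mmHg, vectorised.
#' @export
mean_arterial_pressure <- function(sbp, dbp) {
  if (any(sbp < dbp, na.rm = TRUE))
    stop_cfg("sbp < dbp: readings look transposed")
  sbp / 3 + 2 * dbp / 3
}

#' Average two blood pressure readings
#'
#' Arithmetic mean of the two seated readings. If one reading is missing the
#' available reading is used, with a warning (subjects are excluded only
#' when *no* reading exists).
#'
#' @param first,second The two readings (mmHg); `NA` allowed in one of them.
#' @return Mean reading, vectorised.
#' @export
average_bp <- function(first, second) {
  one_missing <- xor(is.na(first), is.na(second))
  if (any(one_missing))
    warning(sprintf("%d visit(s) have a single BP reading; using it as-is",
                    sum(one_missing)))
  out <- (first + second) / 2
  out[one_missing] <- ifelse(is.na(first[one_missing]),
                             second[one_missing], first[one_missing])
  out
}

#' Build lagged exposure features for visit dates
#'
#' For each visit date and pollutant, the series value 0 to `max_lag` days
#' before the visit.
#'
#' @param series Daily exposure `data.frame` with a `date` column (from
#'   [simulate_exposure_series()] or [read_exposure_csv()]).
#' @param dates Visit dates (`Date` vector, duplicates allowed).
#' @param pollutants Columns of `series` to lag.
#' @param max_lag Maximum lag in days (default 3).
#' @return `data.frame(date, pollutant, lag, value)` in long format.
#' @export
build_lag_features <- function(series, dates,
                               pollutants = c("pm10", "no2", "so2"),
                               max_lag = 3) {
  udates <- sort(unique(dates))
  need <- seq(min(udates) - max_lag, max(udates), by = "day")
  missing_days <- need[!need %in% series$date]
  if (length(missing_days))
    stop_cfg("exposure series does not cover %s",
             as.character(missing_days[1]))
  out <- expand.grid(date = udates, pollutant = pollutants, lag = 0:max_lag,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  idx <- match(out$date - out$lag, series$date)
  out$value <- vapply(seq_len(nrow(out)), function(i)
    series[[out$pollutant[i]]][idx[i]], 0)
  out[order(out$pollutant, out$date, out$lag), , drop = FALSE]
}

#' Scale values to their interquartile range
#'
#' Effect estimates downstream are expressed per IQR increase in the
#' pollutant; this divides values by `Q3 - Q1` of the supplied values
#' (linear-interpolation "type 7" quantiles by default).
#'
#' @param values Numeric vector (>= 4 distinct values) — conventionally the
#'   pollutant restricted to the analysis (survey) days.
#' @param type Quantile type passed to [stats::quantile()].
#' @return List with `scaled` (values / IQR) and `iqr`.
#' @export
iqr_scale <- function(values, type = 7) {
  v <- values[!is.na(values)]
  if (length(unique(v)) < 4) stop_cfg("need >= 4 distinct values for an IQR")
  q <- unname(quantile(v, c(0.25, 0.75), type = type, names = FALSE))
  iqr <- q[2] - q[1]
  if (iqr <= 0) stop_cfg("IQR is zero; cannot scale")
  list(scaled = values / iqr, iqr = iqr)
}

#' Log-transform heart rate variability outcomes
#'
#' SDNN, RMSSD, LF and HF are approximately log-normal; the analysis uses
#' their natural logarithms. Raw columns are left untouched and `log_*`
#' columns are added.
#'
#' @param panel Panel `data.frame` with positive `sdnn`, `rmssd`, `lf`, `hf`.
#' @return The panel with `log_sdnn`, `log_rmssd`, `log_lf`, `log_hf` added.
#' @export
log_transform_hrv <- function(panel) {
  for (v in hrv_outcomes) {
    if (!v %in% names(panel)) next
    bad <- which(!is.na(panel[[v]]) & panel[[v]] <= 0)
    if (length(bad))
      stop_cfg("non-positive %s at rows: %s", v,
               paste(head(bad, 5), collapse = ", "))
    panel[[paste0("log_", v)]] <- log(panel[[v]])
  }
  panel
}

#' Derive analysis outcome columns
#'
#' Adds mean arterial pressure (`map`) and the log-HRV columns to a raw
#' panel.
#'
#' @param panel Panel with `sbp`, `dbp` and HRV columns.
#' @return Augmented panel.
#' @export
derive_outcomes <- function(panel) {
  if (all(c("sbp", "dbp") %in% names(panel)))
    panel$map <- mean_arterial_pressure(panel$sbp, panel$dbp)
  log_transform_hrv(panel)
}

#' Attach lagged exposure and apparent-temperature columns to a panel
#'
#' Computes apparent temperature for the daily series and merges, for every
#' pollutant and lag 0..`max_lag`, columns `<pollutant>_lag<k>` and
#' `atemp_lag<k>` onto the panel by visit date. Apparent temperature enters
#' downstream models at the same lag as the pollutant under test.
#'
#' @param panel Long panel with a `date` column.
#' @param exposures Daily exposure series.
#' @param pollutants Pollutant columns to lag.
#' @param max_lag Maximum lag (default 3).
#' @return The panel with lag columns added; visits without full exposure
#'   coverage raise an error naming the missing date.
#' @export
prepare_analysis_panel <- function(panel, exposures,
                                   pollutants = c("pm10", "no2", "so2"),
                                   max_lag = 3) {
  exposures$atemp <- apparent_temperature(exposures$mean_temp,
                                          exposures$dew_point)
  feats <- build_lag_features(exposures, panel$date,
                              pollutants = c(pollutants, "atemp"),
                              max_lag = max_lag)
  for (p in unique(feats$pollutant)) {
    for (k in 0:max_lag) {
      sub <- feats[feats$pollutant == p & feats$lag == k, ]
      panel[[sprintf("%s_lag%d", p, k)]] <- sub$value[match(panel$date,
                                                            sub$date)]
    }
  }
  derive_outcomes(panel)
}
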