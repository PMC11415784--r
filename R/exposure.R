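#' County-specific extreme-temperature thresholds
#'
#' Computes, for each county, the hot-day and cold-day temperature cutoffs as
#' empirical percentiles of its pooled baseline daily mean temperatures. The
#' conventional definition flags a day as extremely hot when its daily mean
#' exceeds the 97.5th percentile of the county's baseline (historical) daily
#' means, and extremely cold when it falls below the 2.5th percentile; the
#' (99, 1) pair is the usual sensitivity variant.
#'
#' Percentiles use linear interpolation between order statistics
#' ([stats::quantile()] type 7). Comparisons downstream are strict, so a day
#' exactly at a threshold is not extreme.
#'
#' @param daily_temps data frame with columns `county_id`, `date` (Date),
#'   `temp_C` (daily mean temperature, Celsius).
#' @param baseline_years optional integer vector of years; when supplied only
#'   days whose year falls in it enter the percentile computation.
#' @param percentiles length-2 numeric `c(hot, cold)` percentile pair on the
#'   0-100 scale. Default `c(97.5, 2.5)`.
#' @param min_days minimum number of baseline days required per county.
#'
#' @return A tibble with one row per county: `county_id`,
#'   `hot_threshold_C`, `cold_threshold_C`, `pct_hot`, `pct_cold`,
#'   `n_baseline_days`.
#' @export
#' @examples
#' temps <- tibble::tibble(
#'   county_id = 1L,
#'   date = seq(as.Date("1990-01-01"), by = "day", length.out = 730),
#'   temp_C = 15 + 10 * sinpi(2 * (1:730) / 365)
#' )
#' compute_thresholds(temps, min_days = 100)
compute_thresholds <- function(daily_temps, baseline_years = NULL,
                               percentiles = c(97.5, 2.5), min_days = 100) {
  check_columns(daily_temps, c("county_id", "date", "temp_C"), "daily_temps")
  stopifnot(length(percentiles) == 2)
  if (percentiles[1] <= percentiles[2]) {
    abort("`percentiles` must be c(hot, cold) with hot > cold.")
  }
  if (!is.null(baseline_years)) {
    yrs <- as.integer(format(daily_temps$date, "%Y"))
    daily_temps <- daily_temps[yrs %in% baseline_years, , drop = FALSE]
  }
  if (any(!is.finite(daily_temps$temp_C))) {
    abort("daily_temps contains non-finite temperatures.")
  }
  out <- daily_temps %>%
    dplyr::group_by(.data$county_id) %>%
    dplyr::summarise(
      hot_threshold_C = quantile(.data$temp_C, percentiles[1] / 100,
        type = 7, names = FALSE
      ),
      cold_threshold_C = quantile(.data$temp_C, percentiles[2] / 100,
        type = 7, names = FALSE
      ),
      n_baseline_days = dplyr::n(),
      .groups = "drop"
    ) %>%
    dplyr::mutate(pct_hot = percentiles[1], pct_cold = percentiles[2])
  short <- out$county_id[out$n_baseline_days < min_days]
  if (length(short) > 0) {
    abort(sprintf(
      "counties with fewer than %d baseline days: %s",
      min_days, paste(short, collapse = ", ")
    ))
  }
  degenerate <- out$county_id[out$cold_threshold_C >= out$hot_threshold_C]
  if (length(degenerate) > 0) {
    abort(sprintf(
      "cold threshold >= hot threshold (degenerate temperature series) for counties: %s",
      paste(degenerate, collapse = ", ")
    ))
  }
  dplyr::select(
    out, "county_id", "hot_threshold_C", "cold_threshold_C",
    "pct_hot", "pct_cold", "n_baseline_days"
  )
}

#' Monthly extreme-day counts
#'
#' Converts a daily temperature series into a county-by-month panel of
#' extreme heat day counts (daily mean strictly above the county hot
#' threshold) and extreme cold day counts (strictly below the cold
#' threshold). A single day can never count as both.
#'
#' @param daily_temps data frame with `county_id`, `date`, `temp_C`.
#' @param thresholds output of [compute_thresholds()]; must cover every
#'   county present in `daily_temps`.
#' @param lags if `TRUE`, append one-month-lagged counts
#'   (`n_hot_days_lag1`, `n_cold_days_lag1`); the first month of each county
#'   series gets `NA` lags.
#'
#' @return A tibble `county_id`, `year`, `month`, `n_hot_days`,
#'   `n_cold_days` (plus lag columns when requested), ordered by county and
#'   time.
#' @export
count_extreme_days <- function(daily_temps, thresholds, lags = FALSE) {
  check_columns(daily_temps, c("county_id", "date", "temp_C"), "daily_temps")
  check_columns(
    thresholds, c("county_id", "hot_threshold_C", "cold_threshold_C"),
    "thresholds"
  )
  uncovered <- setdiff(
    unique(daily_temps$county_id),
    unique(thresholds$county_id)
  )
  if (length(uncovered) > 0) {
    abort(sprintf(
      "thresholds do not cover counties: %s",
      paste(uncovered, collapse = ", ")
    ))
  }
  panel <- daily_temps %>%
    dplyr::inner_join(
      dplyr::select(
        thresholds, "county_id", "hot_threshold_C", "cold_threshold_C"
      ),
      by = "county_id"
    ) %>%
    dplyr::mutate(
      year = as.integer(format(.data$date, "%Y")),
      month = as.integer(format(.data$date, "%m"))
    ) %>%
    dplyr::group_by(.data$county_id, .data$year, .data$month) %>%
    dplyr::summarise(
      n_hot_days = sum(.data$temp_C > .data$hot_threshold_C),
      n_cold_days = sum(.data$temp_C < .data$cold_threshold_C),
      .groups = "drop"
    ) %>%
    dplyr::arrange(.data$county_id, .data$year, .data$month)
  if (lags) {
    panel <- panel %>%
      dplyr::group_by(.data$county_id) %>%
      dplyr::mutate(
        n_hot_days_lag1 = dplyr::lag(.data$n_hot_days),
        n_cold_days_lag1 = dplyr::lag(.data$n_cold_days)
      ) %>%
      dplyr::ungroup()
  }
  panel
}

#' Heat index (apparent temperature)
#'
#' The US National Weather Service heat-index regression (Rothfusz), with the
#' simple-formula fallback below the 80 F regime and the published low- and
#' high-humidity adjustment terms. The regression is Fahrenheit-native;
#' inputs and outputs here are Celsius.
#'
#' @param temp_C air temperature, Celsius (typically the daily maximum when
#'   used to define apparent-temperature exposure).
#' @param rh_pct relative humidity, percent, in `[0, 100]`.
#'
#' @return Apparent temperature in Celsius, same length as the inputs.
#' @export
#' @examples
#' heat_index(32.2, 70) # about 40.5 C (105 F)
heat_index <- function(temp_C, rh_pct) {
  if (any(rh_pct < 0 | rh_pct > 100, na.rm = TRUE)) {
    abort("relative humidity must be between 0 and 100.")
  }
  n <- max(length(temp_C), length(rh_pct))
  t_f <- rep_len(temp_C, n) * 9 / 5 + 32
  rh <- rep_len(rh_pct, n)
  # Steadman-style simple average, used alone when it stays below 80 F
  hi <- 0.5 * (t_f + 61 + (t_f - 68) * 1.2 + rh * 0.094)
  use_full <- (hi + t_f) / 2 >= 80
  if (any(use_full)) {
    tt <- t_f[use_full]
    rr <- rh[use_full]
    full <- -42.379 + 2.04901523 * tt + 10.14333127 * rr -
      0.22475541 * tt * rr - 0.00683783 * tt^2 - 0.05481717 * rr^2 +
      0.00122874 * tt^2 * rr + 0.00085282 * tt * rr^2 -
      0.00000199 * tt^2 * rr^2
    low_rh <- rr < 13 & tt >= 80 & tt <= 112
    full[low_rh] <- full[low_rh] -
      ((13 - rr[low_rh]) / 4) * sqrt((17 - abs(tt[low_rh] - 95)) / 17)
    high_rh <- rr > 85 & tt >= 80 & tt <= 87
    full[high_rh] <- full[high_rh] +
      ((rr[high_rh] - 85) / 10) * ((87 - tt[high_rh]) / 2)
    hi[use_full] <- full
  }
  (hi - 32) * 5 / 9
}

#' Collapse per-GCM exposure panels to climatological means and their
#' ensemble mean
#'
#' For projection-period exposure, each global climate model (GCM)
#' contributes a multi-year county-by-month panel. This collapses each GCM's
#' panel to the mean count per county and calendar month across the
#' projection years (a 30-year mean in the full-scale analysis), and then
#' averages those means, unweighted, across GCMs. Both levels are returned:
#' excess-death projection runs per GCM and averages deaths afterwards, while
#' the ensemble-mean exposure is a convenient summary.
#'
#' @param per_gcm_panels data frame with columns `gcm`, `county_id`, `year`,
#'   `month`, `n_hot_days`, `n_cold_days` (a stacked set of
#'   [count_extreme_days()] panels).
#'
#' @return A list with `per_gcm` (tibble `gcm`, `county_id`, `month`,
#'   `n_hot_days`, `n_cold_days`, multi-year means) and `ensemble` (same
#'   without `gcm`, averaged across GCMs).
#' @export
gcm_ensemble_exposure <- function(per_gcm_panels) {
  check_columns(
    per_gcm_panels,
    c("gcm", "county_id", "year", "month", "n_hot_days", "n_cold_days"),
    "per_gcm_panels"
  )
  county_sets <- per_gcm_panels %>%
    dplyr::distinct(.data$gcm, .data$county_id) %>%
    dplyr::count(.data$gcm)
  if (dplyr::n_distinct(county_sets$n) > 1) {
    abort("GCM panels do not share a common county set.")
  }
  per_gcm <- per_gcm_panels %>%
    dplyr::group_by(.data$gcm, .data$county_id, .data$month) %>%
    dplyr::summarise(
      n_hot_days = mean(.data$n_hot_days),
      n_cold_days = mean(.data$n_cold_days),
      .groups = "drop"
    )
  ensemble <- per_gcm %>%
    dplyr::group_by(.data$county_id, .data$month) %>%
    dplyr::summarise(
      n_hot_days = mean(.data$n_hot_days),
      n_cold_days = mean(.data$n_cold_days),
      .groups = "drop"
    )
  list(per_gcm = per_gcm, ensemble = ensemble)
}

#' Average centroid temperature series within counties
#'
#' Hook for grid-to-county aggregation: the county daily mean is the
#' unweighted mean over the supplied grid-centroid series falling in that
#' county. Raster extraction itself is upstream of this package.
#'
#' @param centroid_temps data frame with `county_id`, `centroid_id`, `date`,
#'   `temp_C`.
#' @return A tibble `county_id`, `date`, `temp_C`.
#' @export
aggregate_centroids <- function(centroid_temps) {
  check_columns(
    centroid_temps, c("county_id", "centroid_id", "date", "temp_C"),
    "centroid_temps"
  )
  centroid_temps %>%
    dplyr::group_by(.data$county_id, .data$date) %>%
    dplyr::summarise(temp_C = mean(.data$temp_C), .groups = "drop")
}
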