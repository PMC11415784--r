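#' Directly age-standardised mortality rates
#'
#' Collapses stratum-specific rates to a single adjusted rate per
#' county-month by weighting each age group's rate by its share of a fixed
#' standard population (classically the 2000 US Census; in synthetic runs
#' the simulated base-period population).
#'
#' @param mortality panel with `county_id`, `year`, `month`, `age_group`,
#'   `deaths`, `population`, `rate` (per 100k).
#' @param standard_pop tibble `age_group`, `population` defining the
#'   standard weights.
#' @return A tibble `county_id`, `year`, `month`, `deaths`, `population`,
#'   `rate_adjusted` (per 100k).
#' @export
age_adjust <- function(mortality, standard_pop) {
  check_columns(
    mortality, c("county_id", "year", "month", "age_group", "rate"),
    "mortality"
  )
  check_columns(standard_pop, c("age_group", "population"), "standard_pop")
  w <- standard_pop$population / sum(standard_pop$population)
  names(w) <- standard_pop$age_group
  missing <- setdiff(unique(mortality$age_group), names(w))
  if (length(missing) > 0) {
    abort(sprintf(
      "standard population missing age group(s): %s",
      paste(missing, collapse = ", ")
    ))
  }
  mortality %>%
    dplyr::group_by(.data$county_id, .data$year, .data$month) %>%
    dplyr::summarise(
      deaths = sum(.data$deaths),
      population = sum(.data$population),
      rate_adjusted = sum(.data$rate * w[.data$age_group]),
      .groups = "drop"
    )
}

validate_mortality <- function(mortality) {
  bad <- which(mortality$population <= 0)
  if (length(bad) > 0) {
    abort(sprintf(
      "non-positive population in mortality panel row(s): %s",
      paste(utils::head(bad, 5), collapse = ", ")
    ))
  }
  bad <- which(mortality$deaths < 0)
  if (length(bad) > 0) {
    abort(sprintf(
      "negative deaths in mortality panel row(s): %s",
      paste(utils::head(bad, 5), collapse = ", ")
    ))
  }
  invisible(mortality)
}

# exposure stage for one definition variant
variant_exposure <- function(study, percentiles = c(97.5, 2.5),
                             lags = FALSE, use_heat_index = FALSE,
                             rh = 50, scenarios = valid_scenarios) {
  transform <- if (use_heat_index) {
    function(df) dplyr::mutate(df, temp_C = heat_index(.data$temp_C, rh))
  } else {
    identity
  }
  daily <- study$temps$daily
  thresholds <- compute_thresholds(
    transform(dplyr::filter(daily, .data$period == "baseline")),
    percentiles = percentiles
  )
  current <- count_extreme_days(
    transform(dplyr::filter(daily, .data$period == "current")),
    thresholds,
    lags = lags
  )
  projected <- purrr::map(scenarios, function(scen) {
    pathway <- scenario_pathway(scen)
    stacked <- purrr::map(seq_len(study$config$n_gcms), function(g) {
      count_extreme_days(
        transform(gcm_daily(study$temps, g, pathway)), thresholds
      ) %>%
        dplyr::mutate(gcm = g, .before = 1)
    }) %>% dplyr::bind_rows()
    collapsed <- gcm_ensemble_exposure(stacked)$per_gcm
    if (lags) {
      # lag of a climatological calendar-month mean is the previous
      # calendar month's mean (cyclic across the year boundary)
      prev <- collapsed %>%
        dplyr::mutate(month = ifelse(.data$month == 12, 1, .data$month + 1)) %>%
        dplyr::rename(
          n_hot_days_lag1 = "n_hot_days", n_cold_days_lag1 = "n_cold_days"
        )
      collapsed <- dplyr::inner_join(
        collapsed, prev,
        by = c("gcm", "county_id", "month")
      )
    }
    collapsed
  })
  names(projected) <- scenarios
  list(
    thresholds = thresholds, current = current, projected = projected,
    lags = lags
  )
}

# fit both age-group models on a mortality panel joined to an exposure panel
fit_age_groups <- function(study, exposure, neighbors, smoothing = TRUE,
                           covariates = "covariate1",
                           outcome = "rate", cluster = NULL) {
  exp_cols <- intersect(
    c("n_hot_days", "n_cold_days", "n_hot_days_lag1", "n_cold_days_lag1"),
    names(exposure$current)
  )
  panel <- study$mortality %>%
    dplyr::select(-"n_hot_days", -"n_cold_days") %>%
    dplyr::inner_join(exposure$current, by = c("county_id", "year", "month"))
  validate_mortality(panel)
  panel <- smooth_mortality(panel, neighbors, enabled = smoothing)
  fits <- purrr::map(c("older", "younger"), function(grp) {
    ppml_fit(
      dplyr::filter(panel, .data$age_group == grp),
      exposure = exp_cols, covariates = covariates,
      outcome = outcome, cluster = cluster
    )
  })
  names(fits) <- c("older", "younger")
  fits
}

project_age_groups <- function(fits, exposure, study, scenario) {
  proj <- purrr::imap(fits, function(f, grp) {
    pop <- study$pop_projection %>%
      dplyr::filter(.data$scenario == !!scenario, .data$age_group == grp) %>%
      dplyr::select("county_id", "population")
    project_excess(f, exposure$projected[[scenario]], pop, scenario)
  })
  combine_projections(proj)
}

#' Run the full synthetic pipeline end to end
#'
#' Simulate, count exposure, smooth rates, fit the two age-group PPML
#' models, attribute current-period excess deaths, and project both paired
#' scenarios. When `out_dir` is given, every stage's table is written as CSV
#' together with a JSON manifest recording the seed, a config hash, package
#' version, and per-stage row counts.
#'
#' @param config a [synthetic_config()].
#' @param out_dir optional output directory (created if needed).
#' @param smoothing apply spatial empirical Bayes smoothing before fitting.
#' @param percentiles extreme-day percentile pair.
#' @param scenarios scenarios to project.
#' @return A list of class `tempmort_run`: `study`, `exposure`, `fits`,
#'   `attribution` (stratified report), `projections` (one per scenario),
#'   `manifest`.
#' @export
run_pipeline <- function(config = synthetic_config(), out_dir = NULL,
                         smoothing = TRUE, percentiles = c(97.5, 2.5),
                         scenarios = valid_scenarios) {
  study <- simulate_study(config)
  validate_mortality(study$mortality)
  neighbors <- build_grid_neighbors(config$grid_shape[1], config$grid_shape[2])
  exposure <- variant_exposure(study,
    percentiles = percentiles, scenarios = scenarios
  )
  fits <- fit_age_groups(study, exposure, neighbors, smoothing = smoothing)
  pops <- c(
    older = sum(study$counties$pop_older),
    younger = sum(study$counties$pop_younger)
  )
  attribution <- stratified_report(fits, populations = pops)
  projections <- purrr::map(
    scenarios, ~ project_age_groups(fits, exposure, study, .x)
  )
  names(projections) <- scenarios

  stages <- tibble::tibble(
    stage = c(
      "simulate", "exposure", "smooth", "fit", "attribute", "project"
    ),
    rows = c(
      nrow(study$mortality), nrow(exposure$current),
      nrow(study$mortality), sum(vapply(fits, function(f) f$nobs, 1L)),
      nrow(attribution),
      sum(vapply(projections, function(p) nrow(p$per_gcm), 1L))
    )
  )
  manifest <- list(
    package = "tempmort",
    version = as.character(utils::packageVersion("tempmort")),
    seed = config$seed,
    config_hash = rlang::hash(unclass(config)),
    smoothing = smoothing,
    percentiles = percentiles,
    scenarios = scenarios,
    stages = stages
  )
  result <- structure(
    list(
      study = study, exposure = exposure, fits = fits,
      attribution = attribution, projections = projections,
      manifest = manifest
    ),
    class = "tempmort_run"
  )
  if (!is.null(out_dir)) write_run(result, out_dir)
  result
}

write_run <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name) {
    readr::write_csv(df, file.path(out_dir, paste0(name, ".csv")))
  }
  w(result$study$mortality, "mortality")
  w(result$exposure$current, "exposure_current")
  w(result$exposure$thresholds, "thresholds")
  w(result$attribution, "attribution")
  for (scen in names(result$projections)) {
    tag <- gsub("[^a-z0-9]+", "_", scen)
    w(result$projections[[scen]]$summary, paste0("projection_", tag))
    w(result$projections[[scen]]$per_gcm, paste0("projection_per_gcm_", tag))
  }
  for (grp in names(result$fits)) {
    w(tidy(result$fits[[grp]]), paste0("coefficients_", grp))
  }
  jsonlite::write_json(
    result$manifest, file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(out_dir)
}

#' Sensitivity analyses across exposure definitions
#'
#' Reruns exposure counting, model fitting, attribution, and projection for
#' each requested variant — the primary (97.5/2.5) percentile definition,
#' the stricter (99, 1) pair, one-month-lagged exposure terms, and the
#' heat-index (apparent temperature) exposure scale — and reports them side
#' by side.
#'
#' @param study a [simulate_study()] result.
#' @param variants subset of `c("primary", "pct99", "lags", "heat_index")`.
#' @param scenario scenario used for the projected column.
#' @param rh relative humidity (percent) assumed for the heat-index variant.
#' @param smoothing apply rate smoothing before fitting.
#' @return A tibble `variant`, `component`, `current_excess`,
#'   `projected_excess`, `pct_change`.
#' @export
sensitivity_suite <- function(study,
                              variants = c(
                                "primary", "pct99", "lags", "heat_index"
                              ),
                              scenario = "ssp2-4.5", rh = 50,
                              smoothing = TRUE) {
  variants <- match.arg(variants, several.ok = TRUE)
  neighbors <- build_grid_neighbors(
    study$config$grid_shape[1], study$config$grid_shape[2]
  )
  purrr::map(variants, function(v) {
    exposure <- switch(v,
      primary = variant_exposure(study, scenarios = scenario),
      pct99 = variant_exposure(study,
        percentiles = c(99, 1), scenarios = scenario
      ),
      lags = variant_exposure(study, lags = TRUE, scenarios = scenario),
      heat_index = variant_exposure(study,
        use_heat_index = TRUE, rh = rh, scenarios = scenario
      )
    )
    fits <- fit_age_groups(study, exposure, neighbors, smoothing = smoothing)
    proj <- project_age_groups(fits, exposure, study, scenario)
    proj$summary %>%
      dplyr::transmute(
        variant = v,
        component = .data$component,
        current_excess = .data$current_excess,
        projected_excess = .data$excess_annual,
        pct_change = .data$pct_change
      )
  }) %>% dplyr::bind_rows()
}

#' @export
print.tempmort_run <- function(x, ...) {
  cat("<tempmort_run>\n")
  cat("attribution (current period):\n")
  print(x$attribution, n = Inf)
  for (scen in names(x$projections)) {
    cat(sprintf("projection %s:\n", scen))
    print(x$projections[[scen]]$summary, n = Inf)
  }
  invisible(x)
}
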