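#' Configuration for a synthetic temperature-mortality study
#'
#' Defines the scale, planted effect sizes, and climate/population scenario
#' parameters of a fully synthetic study with known ground truth. Defaults
#' give a toy-scale analogue of a national county-level analysis: 100
#' counties on a 10 x 10 grid, three non-overlapping eras (a historical
#' baseline used only for thresholds, a current analysis period, and a
#' mid-century projection period), a 20-model climate ensemble, and planted
#' per-extreme-day log-rate effects of published magnitude (about 0.09% and
#' 0.17% higher mortality per extreme heat day for older and younger adults,
#' 0.26% and 0.27% per extreme cold day).
#'
#' @param n_counties number of counties; must equal `prod(grid_shape)`.
#' @param grid_shape `c(rows, cols)` of the synthetic county grid (used for
#'   rook adjacency in smoothing).
#' @param baseline_years,current_years,projection_years integer year vectors;
#'   must be non-overlapping and ordered baseline < current < projection.
#' @param n_gcms number of climate models in the synthetic ensemble.
#' @param beta_heat,beta_cold named numeric `c(older = , younger = )` true
#'   log-rate effects per extreme day.
#' @param warming_shift_mean_C named numeric `c(rcp45 = , rcp85 = )` mean
#'   constant warming shift (Celsius) added to projection-period daily
#'   temperatures, per emissions pathway.
#' @param warming_shift_sd_C standard deviation of the per-GCM shift draw.
#' @param base_rate named numeric `c(older = , younger = )` baseline
#'   mortality, deaths per 100,000 persons per month.
#' @param pop_range `c(min, max)` adult population per county. The default
#'   makes the 100 synthetic counties partition a national-scale adult
#'   population (about 275 million in total), so the toy panel carries
#'   statistical information comparable to a full national county panel and
#'   parameter-recovery tests run at realistic precision.
#' @param older_fraction share of county adults aged 65+.
#' @param pop_growth named list by scenario (`"ssp2-4.5"`, `"ssp5-8.5"`) of
#'   named growth factors per age group applied to current populations.
#' @param temp_noise_sd daily temperature AR(1) innovation scale, Celsius.
#' @param ar1_rho day-to-day AR(1) persistence of temperature noise (0.7
#'   clusters threshold exceedances into synthetic heat waves / cold snaps).
#' @param seed integer RNG seed; every simulated object is a deterministic
#'   function of the config including this seed.
#'
#' @return An object of class `synthetic_config` (a validated list).
#' @export
synthetic_config <- function(n_counties = 100,
                             grid_shape = c(10, 10),
                             baseline_years = 1991:1995,
                             current_years = 2008:2012,
                             projection_years = 2046:2050,
                             n_gcms = 20,
                             beta_heat = c(older = log(1.0009), younger = log(1.0017)),
                             beta_cold = c(older = log(1.0026), younger = log(1.0027)),
                             warming_shift_mean_C = c(rcp45 = 2.0, rcp85 = 3.0),
                             warming_shift_sd_C = 0.5,
                             base_rate = c(older = 350, younger = 30),
                             pop_range = c(500000, 5000000),
                             older_fraction = 0.225,
                             pop_growth = list(
                               "ssp2-4.5" = c(older = 1.190, younger = 0.868),
                               "ssp5-8.5" = c(older = 1.350, younger = 0.985)
                             ),
                             temp_noise_sd = 3,
                             ar1_rho = 0.7,
                             seed = 1L) {
  cfg <- list(
    n_counties = as.integer(n_counties), grid_shape = as.integer(grid_shape),
    baseline_years = as.integer(baseline_years),
    current_years = as.integer(current_years),
    projection_years = as.integer(projection_years),
    n_gcms = as.integer(n_gcms),
    beta_heat = beta_heat, beta_cold = beta_cold,
    warming_shift_mean_C = warming_shift_mean_C,
    warming_shift_sd_C = warming_shift_sd_C,
    base_rate = base_rate, pop_range = pop_range,
    older_fraction = older_fraction, pop_growth = pop_growth,
    temp_noise_sd = temp_noise_sd, ar1_rho = ar1_rho,
    seed = as.integer(seed)
  )
  validate_synthetic_config(cfg)
  structure(cfg, class = "synthetic_config")
}

validate_synthetic_config <- function(cfg) {
  if (cfg$n_counties < 1) abort("n_counties must be positive.")
  if (prod(cfg$grid_shape) != cfg$n_counties) {
    abort("n_counties must equal prod(grid_shape).")
  }
  for (f in c("baseline_years", "current_years", "projection_years")) {
    if (length(cfg[[f]]) == 0) abort(sprintf("%s is empty.", f))
  }
  if (max(cfg$baseline_years) >= min(cfg$current_years) ||
    max(cfg$current_years) >= min(cfg$projection_years)) {
    abort("year ranges must be non-overlapping and ordered baseline < current < projection.")
  }
  if (cfg$n_gcms < 1) abort("n_gcms must be >= 1.")
  if (any(cfg$base_rate <= 0)) abort("base_rate must be positive.")
  if (any(cfg$pop_range <= 0)) abort("populations must be positive.")
  groups <- c("older", "younger")
  for (f in c("beta_heat", "beta_cold", "base_rate")) {
    if (!all(groups %in% names(cfg[[f]]))) {
      abort(sprintf("%s must be named with 'older' and 'younger'.", f))
    }
  }
  invisible(cfg)
}

county_dates <- function(years) {
  seq(as.Date(sprintf("%d-01-01", min(years))),
    as.Date(sprintf("%d-12-31", max(years))),
    by = "day"
  )
}

#' Simulate county daily mean temperature series
#'
#' Each county follows a sinusoidal annual climatology with county-specific
#' mean, amplitude, and phase, plus AR(1) day-to-day noise. The projection
#' period reuses the same generating process; each GCM and emissions pathway
#' adds one constant warming shift, drawn once per GCM from
#' `N(warming_shift_mean_C[pathway], warming_shift_sd_C)`. Shifts are
#' returned separately so the per-GCM daily series (base projection series
#' plus shift) never needs to be materialised for all models at once.
#'
#' @param config a [synthetic_config()].
#' @return A list of class `tempmort_temps`: `daily` (tibble `county_id`,
#'   `date`, `temp_C`, `period` in baseline/current/projection),
#'   `gcm_shifts` (tibble `gcm`, `scenario`, `shift_C`), and the
#'   county climatology parameters in `climatology`.
#' @export
simulate_temperatures <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  nc <- config$n_counties
  clim <- tibble::tibble(
    county_id = seq_len(nc),
    mean_C = runif(nc, 8, 18),
    amplitude_C = runif(nc, 10, 14),
    phase = runif(nc, -0.2, 0.2)
  )
  periods <- list(
    baseline = config$baseline_years,
    current = config$current_years,
    projection = config$projection_years
  )
  daily <- purrr::imap(periods, function(years, label) {
    dates <- county_dates(years)
    doy <- as.integer(format(dates, "%j"))
    nd <- length(dates)
    temp <- purrr::pmap(clim, function(county_id, mean_C, amplitude_C, phase) {
      seasonal <- mean_C +
        amplitude_C * sin(2 * pi * doy / 365 - pi / 2 + phase)
      if (config$temp_noise_sd > 0) {
        innov <- rnorm(nd, 0, config$temp_noise_sd)
        noise <- as.numeric(stats::filter(innov, config$ar1_rho,
          method = "recursive"
        ))
      } else {
        noise <- 0
      }
      seasonal + noise
    })
    tibble::tibble(
      county_id = rep(clim$county_id, each = nd),
      date = rep(dates, nc),
      temp_C = unlist(temp),
      period = label
    )
  }) %>% dplyr::bind_rows()
  shifts <- tidyr::expand_grid(
    scenario = names(config$warming_shift_mean_C),
    gcm = seq_len(config$n_gcms)
  ) %>%
    dplyr::mutate(
      shift_C = rnorm(
        dplyr::n(),
        config$warming_shift_mean_C[.data$scenario],
        config$warming_shift_sd_C
      )
    )
  structure(
    list(daily = daily, gcm_shifts = shifts, climatology = clim,
         config = config),
    class = "tempmort_temps"
  )
}

#' Projection-period daily series for one GCM
#'
#' @param temps a [simulate_temperatures()] result.
#' @param gcm GCM index.
#' @param scenario pathway name matching `names(warming_shift_mean_C)`
#'   (by convention `rcp45` / `rcp85`).
#' @return Daily tibble for the projection period with the GCM's constant
#'   shift applied.
#' @export
gcm_daily <- function(temps, gcm, scenario) {
  stopifnot(inherits(temps, "tempmort_temps"))
  row <- temps$gcm_shifts[
    temps$gcm_shifts$gcm == gcm & temps$gcm_shifts$scenario == scenario,
  ]
  if (nrow(row) != 1) abort("unknown gcm/scenario combination.")
  temps$daily %>%
    dplyr::filter(.data$period == "projection") %>%
    dplyr::mutate(temp_C = .data$temp_C + row$shift_C)
}

#' Per-GCM projection exposure panels
#'
#' Counts extreme days in the shifted projection-period series of every GCM
#' under one emissions pathway, against fixed current-period thresholds
#' (identical absolute Celsius cutoffs, as in threshold-based projection).
#'
#' @inheritParams gcm_daily
#' @param thresholds a [compute_thresholds()] table.
#' @return Stacked monthly panels with a `gcm` column, suitable for
#'   [gcm_ensemble_exposure()].
#' @export
gcm_exposure_panels <- function(temps, thresholds, scenario) {
  stopifnot(inherits(temps, "tempmort_temps"))
  purrr::map(seq_len(temps$config$n_gcms), function(g) {
    count_extreme_days(gcm_daily(temps, g, scenario), thresholds) %>%
      dplyr::mutate(gcm = g, .before = 1)
  }) %>% dplyr::bind_rows()
}

#' Simulate a complete synthetic study with known ground truth
#'
#' Generates temperatures, thresholds, current-period exposure, county
#' populations (older/younger adults), scenario population projections, one
#' smooth county-year covariate, and Poisson death counts per county-month
#' and age group from
#' \deqn{deaths \sim Pois(pop/10^5 \cdot base \cdot
#'   e^{\alpha_c + \gamma_m + \delta_y + \beta_h H + \beta_c C})}
#' with known fixed effects and planted \eqn{\beta_h, \beta_c}. The returned
#' truth object carries everything needed to evaluate the closed-form
#' expected excess deaths \eqn{\sum \mu (1 - e^{-\beta_h H - \beta_c C})} at
#' the true parameters.
#'
#' @param config a [synthetic_config()].
#' @return A list of class `tempmort_study` with elements `mortality`
#'   (county-month-age panel: deaths, population, rate per 100k),
#'   `exposure`, `thresholds`, `temps`, `counties` (grid position, region,
#'   metro status, stratum populations), `pop_projection`, and `truth`
#'   (class `tempmort_truth`).
#' @export
simulate_study <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  temps <- simulate_temperatures(config)
  thresholds <- compute_thresholds(
    dplyr::filter(temps$daily, .data$period == "baseline"),
    percentiles = c(97.5, 2.5)
  )
  exposure <- count_extreme_days(
    dplyr::filter(temps$daily, .data$period == "current"), thresholds
  )

  # county frame: grid position, region by quadrant, metro by size
  set.seed(config$seed + 1L)
  nc <- config$n_counties
  rows <- config$grid_shape[1]
  cols <- config$grid_shape[2]
  counties <- tibble::tibble(
    county_id = seq_len(nc),
    grid_row = rep(seq_len(rows), each = cols),
    grid_col = rep(seq_len(cols), rows),
    population = round(runif(nc, config$pop_range[1], config$pop_range[2]))
  ) %>%
    dplyr::mutate(
      region = dplyr::case_when(
        .data$grid_row <= rows / 2 & .data$grid_col <= cols / 2 ~ "Northeast",
        .data$grid_row <= rows / 2 ~ "Midwest",
        .data$grid_col <= cols / 2 ~ "South",
        TRUE ~ "West"
      ),
      metro = ifelse(.data$population > stats::median(.data$population),
        "metro", "nonmetro"
      ),
      pop_older = round(.data$population * config$older_fraction),
      pop_younger = .data$population - .data$pop_older
    )

  # fixed effects (truth)
  county_fe <- rnorm(nc, 0, 0.15)
  month_fe <- 0.12 * cos(2 * pi * (1:12 - 1) / 12) # winter-peaked mortality
  years <- config$current_years
  year_fe <- rnorm(length(years), 0, 0.03)
  names(county_fe) <- as.character(seq_len(nc))
  names(month_fe) <- as.character(1:12)
  names(year_fe) <- as.character(years)

  # one smooth county-year covariate, independent of exposure
  covariate <- tidyr::expand_grid(
    county_id = seq_len(nc), year = years
  ) %>%
    dplyr::group_by(.data$county_id) %>%
    dplyr::mutate(
      covariate1 = cumsum(rnorm(dplyr::n(), 0, 0.5)) + rnorm(1, 0, 1)
    ) %>%
    dplyr::ungroup()

  groups <- c("older", "younger")
  panel <- exposure %>%
    dplyr::inner_join(
      dplyr::select(
        counties, "county_id", "pop_older", "pop_younger",
        "region", "metro"
      ),
      by = "county_id"
    ) %>%
    tidyr::pivot_longer(
      cols = c("pop_older", "pop_younger"),
      names_to = "age_group", names_prefix = "pop_",
      values_to = "population"
    ) %>%
    dplyr::inner_join(covariate, by = c("county_id", "year")) %>%
    dplyr::mutate(
      log_mu = log(.data$population / 1e5) +
        log(config$base_rate[.data$age_group]) +
        county_fe[as.character(.data$county_id)] +
        month_fe[as.character(.data$month)] +
        year_fe[as.character(.data$year)] +
        config$beta_heat[.data$age_group] * .data$n_hot_days +
        config$beta_cold[.data$age_group] * .data$n_cold_days,
      expected_deaths = exp(.data$log_mu)
    )
  if (any(panel$expected_deaths > 1e9)) {
    abort("expected death counts overflow (rate x population too large).")
  }
  panel$deaths <- rpois(nrow(panel), panel$expected_deaths)
  mortality <- panel %>%
    dplyr::mutate(rate = 1e5 * .data$deaths / .data$population) %>%
    dplyr::select(
      "county_id", "year", "month", "age_group", "region", "metro",
      "deaths", "population", "rate", "covariate1",
      "n_hot_days", "n_cold_days"
    )

  pop_projection <- purrr::imap(config$pop_growth, function(growth, scen) {
    counties %>%
      dplyr::transmute(
        scenario = scen,
        county_id = .data$county_id,
        older = round(.data$pop_older * growth[["older"]]),
        younger = round(.data$pop_younger * growth[["younger"]])
      ) %>%
      tidyr::pivot_longer(c("older", "younger"),
        names_to = "age_group", values_to = "population"
      )
  }) %>% dplyr::bind_rows()

  truth <- structure(
    list(
      beta_heat = config$beta_heat, beta_cold = config$beta_cold,
      county_fe = county_fe, month_fe = month_fe, year_fe = year_fe,
      base_rate = config$base_rate,
      gcm_shifts = temps$gcm_shifts,
      expected_panel = dplyr::select(
        panel, "county_id", "year", "month", "age_group",
        "n_hot_days", "n_cold_days", "expected_deaths"
      ),
      n_years = length(years)
    ),
    class = "tempmort_truth"
  )

  structure(
    list(
      mortality = mortality, exposure = exposure, thresholds = thresholds,
      temps = temps, counties = counties, pop_projection = pop_projection,
      truth = truth, config = config
    ),
    class = "tempmort_study"
  )
}

#' Closed-form expected excess deaths under the true parameters
#'
#' Evaluates \eqn{\sum_{ct} \mu_{ct} (1 - e^{-\beta_h H_{ct} - \beta_c
#' C_{ct}})} (or the heat-only / cold-only analogue) on the truth object's
#' expected-count panel, divided by the number of study years to give a mean
#' annual figure. This is the quantity the attribution machinery must
#' reproduce exactly when the true coefficients are injected.
#'
#' @param truth a `tempmort_truth` object from [simulate_study()].
#' @param component one of "heat", "cold", "combined".
#' @param age_group "older", "younger", or "all" (sum of both).
#' @return Mean annual expected excess deaths (scalar).
#' @export
truth_excess <- function(truth, component = c("combined", "heat", "cold"),
                         age_group = "all") {
  stopifnot(inherits(truth, "tempmort_truth"))
  component <- match.arg(component)
  if (component == "combined") {
    # combined = heat + cold as one-at-a-time removals from the joint fit
    return(truth_excess(truth, "heat", age_group) +
      truth_excess(truth, "cold", age_group))
  }
  pan <- truth$expected_panel
  if (age_group != "all") pan <- pan[pan$age_group == age_group, ]
  bh <- truth$beta_heat[pan$age_group]
  bc <- truth$beta_cold[pan$age_group]
  drop_term <- switch(component,
    heat = bh * pan$n_hot_days,
    cold = bc * pan$n_cold_days
  )
  sum(pan$expected_deaths * (1 - exp(-drop_term))) / truth$n_years
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat("<synthetic_config>\n")
  cat(sprintf(
    "  %d counties (%d x %d grid), %d GCMs, seed %d\n",
    x$n_counties, x$grid_shape[1], x$grid_shape[2], x$n_gcms, x$seed
  ))
  cat(sprintf(
    "  years: baseline %d-%d, current %d-%d, projection %d-%d\n",
    min(x$baseline_years), max(x$baseline_years),
    min(x$current_years), max(x$current_years),
    min(x$projection_years), max(x$projection_years)
  ))
  cat(sprintf(
    "  planted %% change per extreme day: heat %.3f/%.3f, cold %.3f/%.3f (older/younger)\n",
    100 * expm1(x$beta_heat[["older"]]), 100 * expm1(x$beta_heat[["younger"]]),
    100 * expm1(x$beta_cold[["older"]]), 100 * expm1(x$beta_cold[["younger"]])
  ))
  invisible(x)
}

#' @export
print.tempmort_study <- function(x, ...) {
  cat("<tempmort_study>\n")
  cat(sprintf(
    "  mortality panel: %d rows (%d counties x %d months x %d age groups)\n",
    nrow(x$mortality), x$config$n_counties,
    12 * length(x$config$current_years), 2
  ))
  cat(sprintf("  ensemble: %d GCMs x %d scenarios\n",
    x$config$n_gcms, length(x$config$pop_growth)))
  invisible(x)
}
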