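valid_scenarios <- c("ssp2-4.5", "ssp5-8.5")

# scenario label -> emissions pathway of its paired temperature projection
scenario_pathway <- function(scenario) {
  switch(scenario,
    "ssp2-4.5" = "rcp45",
    "ssp5-8.5" = "rcp85",
    abort(sprintf(
      "unknown scenario '%s'; valid pairings: %s",
      scenario, paste(valid_scenarios, collapse = ", ")
    ))
  )
}

# baseline (exposure-free) linear predictor of the fit, per county-month
# or per county-year-month, on the rate scale used by the fit
baseline_eta <- function(fit, by_year) {
  x_exp <- as.matrix(fit$data[, fit$exposure_cols, drop = FALSE])
  base <- fit$eta - drop(x_exp %*% fit$coefficients[fit$exposure_cols]) -
    fit$offset
  d <- dplyr::mutate(fit$data, .base_eta = base)
  if (by_year) {
    dplyr::select(
      d, "county_id", "year", "month", base_eta = ".base_eta"
    )
  } else {
    # average across current-period years: mean year effect and mean
    # covariate contribution, frozen for projection
    d %>%
      dplyr::group_by(.data$county_id, .data$month) %>%
      dplyr::summarise(base_eta = mean(.data$.base_eta), .groups = "drop")
  }
}

#' Project excess deaths to a future period under a paired scenario
#'
#' Re-evaluates the counterfactual excess-death formula with projected
#' extreme-day counts (separately for every climate model in the ensemble)
#' and projected population, keeping the regression coefficients, fixed
#' effects, and covariate contributions frozen at their current-period
#' estimates. The emissions pathway of the exposure projection is paired
#' with the population scenario (SSP2 with RCP4.5, SSP5 with RCP8.5). The
#' ensemble-mean excess is the unweighted mean of the per-GCM values;
#' confidence intervals propagate coefficient uncertainty only (climate
#' ensemble spread is reported separately as the per-GCM range).
#'
#' @param fit a current-period [ppml_fit()].
#' @param projected_exposure tibble with `gcm`, `county_id`, `month`
#'   (optionally `year`), and the fit's exposure columns; typically the
#'   `per_gcm` element of [gcm_ensemble_exposure()] (multi-year mean counts
#'   per calendar month) or raw stacked panels from
#'   [gcm_exposure_panels()].
#' @param projected_population tibble `county_id`, `population` for the
#'   stratum being projected.
#' @param scenario `"ssp2-4.5"` or `"ssp5-8.5"`.
#' @param year_effect how current-period year fixed effects enter a
#'   calendar-month projection: `"mean"` (default) or `"last"` (final
#'   year's). Ignored when `projected_exposure` carries a `year` column, in
#'   which case current-period year effects are used year-by-year.
#' @param component components to report.
#' @param conf_level confidence level.
#' @return An object of class `tempmort_projection`: `summary` (tibble
#'   `scenario`, `component`, ensemble-mean `excess_annual`, `se`, `ci_lo`,
#'   `ci_hi`, per-GCM `gcm_min`/`gcm_max`, `current_excess`, `pct_change`,
#'   `pct_ci_lo`, `pct_ci_hi`) and `per_gcm` (tibble `gcm`, `component`,
#'   `excess_annual`).
#' @export
project_excess <- function(fit, projected_exposure, projected_population,
                           scenario = valid_scenarios,
                           year_effect = c("mean", "last"),
                           component = c("combined", "heat", "cold"),
                           conf_level = 0.95) {
  stopifnot(inherits(fit, "tempmort_ppml"))
  scenario <- match.arg(scenario)
  year_effect <- match.arg(year_effect)
  component <- match.arg(component, several.ok = TRUE)
  check_columns(
    projected_exposure, c("gcm", "county_id", "month", fit$exposure),
    "projected_exposure"
  )
  check_columns(
    projected_population, c("county_id", "population"),
    "projected_population"
  )
  if (any(projected_population$population <= 0)) {
    abort("projected population must be strictly positive.")
  }
  new_counties <- setdiff(
    unique(projected_exposure$county_id), unique(fit$data$county_id)
  )
  if (length(new_counties) > 0) {
    abort(sprintf(
      "projected counties absent from fit: %s",
      paste(new_counties, collapse = ", ")
    ))
  }

  by_year <- "year" %in% names(projected_exposure)
  base <- baseline_eta(fit, by_year)
  if (!by_year && year_effect == "last") {
    last_y <- max(fit$data$year)
    shift <- fit$fe_effects$year[[as.character(last_y)]] -
      mean(fit$fe_effects$year)
    base$base_eta <- base$base_eta + shift
  }
  join_keys <- if (by_year) c("county_id", "year", "month") else
    c("county_id", "month")

  heat_cols <- component_cols(fit, "heat")
  cold_cols <- component_cols(fit, "cold")
  ecols <- c(heat_cols, cold_cols)
  beta <- fit$coefficients[ecols]
  V <- fit$vcov[ecols, ecols, drop = FALSE]

  panel <- projected_exposure %>%
    dplyr::inner_join(base, by = join_keys) %>%
    dplyr::inner_join(projected_population, by = "county_id")
  n_years <- if (by_year) dplyr::n_distinct(panel$year) else 1L
  xmat <- as.matrix(panel[, ecols, drop = FALSE])
  s <- drop(xmat %*% beta)
  mu <- exp(panel$base_eta + s) * panel$population / 1e5

  gcm_f <- factor(panel$gcm)
  per_gcm_parts <- purrr::map(levels(gcm_f), function(g) {
    i <- which(gcm_f == g)
    purrr::map(c("heat", "cold"), function(cmp) {
      excess_core(mu[i], xmat[i, , drop = FALSE], beta, heat_cols,
        cold_cols, cmp, n_years)
    }) %>% setNames(c("heat", "cold"))
  })
  names(per_gcm_parts) <- levels(gcm_f)

  per_gcm <- purrr::imap(per_gcm_parts, function(p, g) {
    tibble::tibble(
      gcm = g,
      component = c("heat", "cold", "combined"),
      excess_annual = c(
        p$heat$excess, p$cold$excess, p$heat$excess + p$cold$excess
      )
    )
  }) %>% dplyr::bind_rows()

  current <- excess_deaths(fit,
    component = component, conf_level = conf_level
  )
  cur_grad <- attr(current, "grad")

  summary <- purrr::map(component, function(cmp) {
    vals <- dplyr::filter(per_gcm, .data$component == cmp)$excess_annual
    grads <- purrr::map(per_gcm_parts, function(p) {
      switch(cmp,
        heat = p$heat$grad, cold = p$cold$grad,
        combined = p$heat$grad + p$cold$grad
      )
    })
    g_mean <- Reduce(`+`, grads) / length(grads)
    est <- mean(vals)
    se <- sqrt(drop(t(g_mean) %*% V %*% g_mean))
    ci <- normal_ci(est, se, conf_level)
    cur_row <- dplyr::filter(current, .data$component == cmp)
    pc <- if (cur_row$excess_annual > 0) {
      percent_change(
        cur_row$excess_annual, est,
        vcov = V, grad_current = cur_grad[[cmp]], grad_projected = g_mean,
        conf_level = conf_level
      )
    } else {
      # a non-positive current-period estimate (possible in small or null
      # studies) leaves the relative change undefined
      tibble::tibble(
        pct_change = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_
      )
    }
    tibble::tibble(
      scenario = scenario, component = cmp,
      excess_annual = est, se = se, ci_lo = ci$lo, ci_hi = ci$hi,
      gcm_min = min(vals), gcm_max = max(vals),
      current_excess = cur_row$excess_annual,
      pct_change = pc$pct_change, pct_ci_lo = pc$ci_lo, pct_ci_hi = pc$ci_hi
    )
  }) %>% dplyr::bind_rows()

  structure(
    list(summary = summary, per_gcm = per_gcm, scenario = scenario),
    class = "tempmort_projection"
  )
}

#' Percent change between a current and a projected estimate
#'
#' Computes \eqn{100 (P - C) / C}. When the two estimates are smooth
#' functions of the same coefficient vector (as current and projected excess
#' deaths are), supply their gradients and the shared covariance to obtain a
#' delta-method confidence interval on the ratio.
#'
#' @param current,projected point estimates; `current` must be positive.
#' @param vcov optional coefficient covariance shared by both estimates.
#' @param grad_current,grad_projected gradients of the two estimates with
#'   respect to those coefficients.
#' @param conf_level confidence level.
#' @return A one-row tibble `pct_change`, `ci_lo`, `ci_hi` (intervals `NA`
#'   without covariance information).
#' @export
#' @examples
#' percent_change(8248.6, 19348.7) # 134.6% to one decimal
percent_change <- function(current, projected, vcov = NULL,
                           grad_current = NULL, grad_projected = NULL,
                           conf_level = 0.95) {
  if (any(current <= 0)) abort("current estimate must be positive.")
  pct <- 100 * (projected - current) / current
  if (is.null(vcov)) {
    return(tibble::tibble(pct_change = pct, ci_lo = NA_real_, ci_hi = NA_real_))
  }
  d <- 100 * (grad_projected * current - projected * grad_current) / current^2
  se <- sqrt(drop(t(d) %*% vcov %*% d))
  ci <- normal_ci(pct, se, conf_level)
  tibble::tibble(pct_change = pct, ci_lo = ci$lo, ci_hi = ci$hi)
}

#' Sum projections across independently fitted strata
#'
#' Point estimates and per-GCM values add; variances add because the
#' stratum fits are independent. Percent change versus the current period is
#' recomputed for the summed series.
#'
#' @param projections named list of [project_excess()] results sharing a
#'   scenario and component set.
#' @param currents named list of the matching current-period
#'   [excess_deaths()] tables (for the summed percent-change denominator);
#'   defaults to the `current_excess` column carried by each projection.
#' @return A `tempmort_projection` with aggregated `summary` and `per_gcm`.
#' @export
combine_projections <- function(projections, currents = NULL) {
  stopifnot(length(projections) >= 1)
  scen <- unique(vapply(projections, function(p) p$scenario, ""))
  if (length(scen) > 1) abort("projections mix scenarios.")
  per_gcm <- purrr::map(projections, "per_gcm") %>%
    dplyr::bind_rows() %>%
    dplyr::group_by(.data$gcm, .data$component) %>%
    dplyr::summarise(excess_annual = sum(.data$excess_annual), .groups = "drop")
  summaries <- purrr::map(projections, "summary")
  summary <- dplyr::bind_rows(summaries) %>%
    dplyr::group_by(.data$scenario, .data$component) %>%
    dplyr::summarise(
      excess_annual = sum(.data$excess_annual),
      se = sqrt(sum(.data$se^2)),
      gcm_min = NA_real_, gcm_max = NA_real_,
      current_excess = sum(.data$current_excess),
      .groups = "drop"
    )
  rng <- per_gcm %>%
    dplyr::group_by(.data$component) %>%
    dplyr::summarise(
      gcm_min = min(.data$excess_annual),
      gcm_max = max(.data$excess_annual), .groups = "drop"
    )
  summary$gcm_min <- rng$gcm_min[match(summary$component, rng$component)]
  summary$gcm_max <- rng$gcm_max[match(summary$component, rng$component)]
  ci <- normal_ci(summary$excess_annual, summary$se)
  summary$ci_lo <- ci$lo
  summary$ci_hi <- ci$hi
  summary$pct_change <- ifelse(
    summary$current_excess > 0,
    100 * (summary$excess_annual - summary$current_excess) /
      summary$current_excess,
    NA_real_
  )
  # ratio CI for the sum needs cross-stratum gradient bookkeeping; the
  # stratum-level intervals remain the inferential objects
  summary$pct_ci_lo <- NA_real_
  summary$pct_ci_hi <- NA_real_
  structure(
    list(summary = summary, per_gcm = per_gcm, scenario = scen),
    class = "tempmort_projection"
  )
}

#' @export
print.tempmort_projection <- function(x, ...) {
  cat(sprintf("<tempmort_projection> scenario %s\n", x$scenario))
  print(x$summary, n = Inf)
  invisible(x)
}

#' Bar chart of current versus projected excess deaths
#'
#' @param object a [project_excess()] result.
#' @param ... unused.
#' @return A ggplot comparing current and ensemble-mean projected excess
#'   deaths by component, with coefficient-uncertainty intervals and the
#'   per-GCM range.
#' @method autoplot tempmort_projection
#' @export
autoplot.tempmort_projection <- function(object, ...) {
  s <- object$summary
  df <- dplyr::bind_rows(
    tibble::tibble(
      period = "current", component = s$component,
      excess = s$current_excess, lo = NA_real_, hi = NA_real_
    ),
    tibble::tibble(
      period = paste0("projected (", s$scenario, ")"),
      component = s$component,
      excess = s$excess_annual, lo = s$ci_lo, hi = s$ci_hi
    )
  )
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$component, y = .data$excess, fill = .data$period
  )) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8), width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
      position = ggplot2::position_dodge(width = 0.8), width = 0.2,
      na.rm = TRUE
    ) +
    ggplot2::labs(
      x = NULL, y = "mean annual excess deaths", fill = NULL
    ) +
    ggplot2::theme_minimal()
}
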