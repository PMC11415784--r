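#' Expected deaths per county-month from a PPML fit
#'
#' In rate mode the fitted monthly rate per 100,000 is scaled by
#' `population / 1e5`; in count mode the fitted mean is already a death
#' count. With `panel = NULL` the fit's own estimation sample and converged
#' linear predictor are used, so the Poisson score identity
#' \eqn{\sum \hat\mu = \sum y} holds exactly. For a supplied panel the
#' linear predictor is rebuilt from the recovered fixed effects and
#' coefficients; counties (or months/years) absent from the fit are an
#' error — there is no out-of-sample fixed-effect prediction in the current
#' period.
#'
#' @param fit a [ppml_fit()] object.
#' @param panel optional data frame with the fit's exposure, covariate,
#'   fixed-effect, and population columns.
#' @return The panel with columns `mu_hat` (expected deaths) and `eta_hat`
#'   (linear predictor).
#' @export
predict_expected_deaths <- function(fit, panel = NULL) {
  stopifnot(inherits(fit, "tempmort_ppml"))
  if (is.null(panel)) {
    data <- fit$data
    eta <- fit$eta
  } else {
    data <- tibble::as_tibble(panel)
    eta <- linear_predictor(fit, data)
  }
  mu <- if (fit$outcome == "rate") {
    exp(eta) * data[[fit$pop_col]] / 1e5
  } else {
    exp(eta)
  }
  dplyr::mutate(data, eta_hat = eta, mu_hat = mu)
}

# rebuild the linear predictor for panel rows from stored components
linear_predictor <- function(fit, data) {
  check_columns(
    data,
    unique(c(fit$exposure, fit$fe, fit$covariates, fit$pop_col)), "panel"
  )
  eta <- if (fit$outcome == "count") log(data[[fit$pop_col]] / 1e5) else 0
  for (f in fit$fe) {
    eff <- fit$fe_effects[[f]]
    lev <- as.character(data[[f]])
    unseen <- setdiff(unique(lev), names(eff))
    if (length(unseen) > 0) {
      abort(sprintf(
        "fixed-effect level(s) of '%s' absent from fit: %s",
        f, paste(unseen, collapse = ", ")
      ))
    }
    eta <- eta + eff[lev]
  }
  X <- design_columns(fit, data)
  unname(eta + drop(X %*% fit$coefficients[colnames(X)]))
}

design_columns <- function(fit, data) {
  xs <- list()
  for (v in fit$exposure) {
    if (fit$exposure_spline) {
      b <- predict_rcs(fit$bases[[v]], data[[v]])
      colnames(b) <- paste0(v, "_", colnames(b))
      xs[[v]] <- unclass(b)
    } else {
      xs[[v]] <- matrix(data[[v]], dimnames = list(NULL, v))
    }
  }
  for (v in fit$covariates %||% character()) {
    b <- predict_rcs(fit$bases[[v]], data[[v]])
    colnames(b) <- paste0(v, "_", colnames(b))
    xs[[v]] <- unclass(b)
  }
  do.call(cbind, xs)
}

# columns of the linear exposure specification belonging to each component
component_cols <- function(fit, component) {
  if (fit$exposure_spline) {
    abort("excess-death attribution requires the linear exposure specification.")
  }
  cols <- switch(component,
    heat = grep("hot", fit$exposure_cols, value = TRUE),
    cold = grep("cold", fit$exposure_cols, value = TRUE)
  )
  if (length(cols) == 0) {
    abort(sprintf("no exposure column matches component '%s'.", component))
  }
  cols
}

# core excess computation shared by attribution and projection:
# mu = expected deaths under observed/projected exposure (vector),
# xmat = exposure design (rows aligned with mu), beta over xmat columns.
# Returns annualised excess and its gradient w.r.t. all exposure coefs.
excess_core <- function(mu, xmat, beta, heat_cols, cold_cols, component,
                        n_years) {
  cols <- if (component == "heat") heat_cols else cold_cols
  s <- drop(xmat[, cols, drop = FALSE] %*% beta[cols])
  excess <- sum(mu * (1 - exp(-s))) / n_years
  grad <- setNames(numeric(length(beta)), names(beta))
  for (j in names(beta)) {
    grad[j] <- if (j %in% cols) {
      sum(xmat[, j] * mu) / n_years
    } else {
      sum(xmat[, j] * mu * (1 - exp(-s))) / n_years
    }
  }
  list(excess = excess, grad = grad)
}

#' Counterfactual excess deaths attributable to extreme temperatures
#'
#' Excess deaths are the difference between expected deaths under the
#' observed number of extreme temperature days and expected deaths had no
#' extreme temperature days occurred, with fixed effects and covariates held
#' at their observed values: for extreme heat,
#' \eqn{\sum_{ct} \hat\mu_{ct} (1 - e^{-\hat\beta_h H_{ct}})}, analogously
#' for cold, and combined as their sum (both counterfactuals are taken from
#' the same joint fit, so heat + cold = combined by construction). Totals
#' are divided by the number of study years to give mean annual figures.
#'
#' Confidence intervals propagate the robust covariance of
#' \eqn{(\hat\beta_h, \hat\beta_c)} by the delta method (default) or by
#' parametric simulation of the exposure coefficients from their asymptotic
#' normal distribution.
#'
#' @param fit a [ppml_fit()] with linear exposure terms.
#' @param panel optional panel passed to [predict_expected_deaths()].
#' @param component subset of `c("combined", "heat", "cold")`.
#' @param conf_level confidence level.
#' @param ci_method `"delta"` or `"simulation"`.
#' @param n_draws,seed simulation controls.
#' @return A tibble with one row per component: `component`,
#'   `excess_annual`, `se`, `ci_lo`, `ci_hi`, `n_years`. Gradients and the
#'   exposure-coefficient covariance ride along as attributes `grad` and
#'   `vcov` for downstream percent-change calculations.
#' @export
excess_deaths <- function(fit, panel = NULL,
                          component = c("combined", "heat", "cold"),
                          conf_level = 0.95,
                          ci_method = c("delta", "simulation"),
                          n_draws = 10000, seed = 1L) {
  stopifnot(inherits(fit, "tempmort_ppml"))
  ci_method <- match.arg(ci_method)
  component <- match.arg(component, several.ok = TRUE)
  pred <- predict_expected_deaths(fit, panel)
  heat_cols <- component_cols(fit, "heat")
  cold_cols <- component_cols(fit, "cold")
  ecols <- c(heat_cols, cold_cols)
  xmat <- as.matrix(pred[, ecols, drop = FALSE])
  beta <- fit$coefficients[ecols]
  V <- fit$vcov[ecols, ecols, drop = FALSE]
  n_years <- dplyr::n_distinct(pred[["year"]] %||% 1)

  parts <- purrr::map(c("heat", "cold"), function(cmp) {
    excess_core(pred$mu_hat, xmat, beta, heat_cols, cold_cols, cmp, n_years)
  })
  names(parts) <- c("heat", "cold")
  parts$combined <- list(
    excess = parts$heat$excess + parts$cold$excess,
    grad = parts$heat$grad + parts$cold$grad
  )

  draws <- NULL
  if (ci_method == "simulation") {
    draws <- simulate_beta(beta, V, n_draws, seed)
  }
  rows <- purrr::map(component, function(cmp) {
    pt <- parts[[cmp]]
    if (ci_method == "delta") {
      se <- sqrt(drop(t(pt$grad) %*% V %*% pt$grad))
      ci <- normal_ci(pt$excess, se, conf_level)
      lo <- ci$lo
      hi <- ci$hi
    } else {
      sims <- apply(draws, 1, function(b) {
        h <- excess_core(pred$mu_hat, xmat, b, heat_cols, cold_cols,
          "heat", n_years)$excess
        c <- excess_core(pred$mu_hat, xmat, b, heat_cols, cold_cols,
          "cold", n_years)$excess
        switch(cmp, heat = h, cold = c, combined = h + c)
      })
      se <- sd(sims)
      qs <- quantile(sims, c((1 - conf_level) / 2, 1 - (1 - conf_level) / 2),
        names = FALSE
      )
      lo <- qs[1]
      hi <- qs[2]
    }
    tibble::tibble(
      component = cmp, excess_annual = pt$excess, se = se,
      ci_lo = lo, ci_hi = hi, n_years = n_years
    )
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "grad") <- purrr::map(parts[component], "grad")
  attr(out, "vcov") <- V
  out
}

simulate_beta <- function(beta, V, n_draws, seed) {
  set.seed(seed)
  L <- chol(V + diag(1e-14, nrow(V)))
  matrix(rnorm(n_draws * length(beta)), n_draws) %*% L +
    matrix(beta, n_draws, length(beta), byrow = TRUE)
}

#' Rescale an excess-death estimate to a per-million rate
#'
#' Linear rescaling of the estimate and both interval endpoints by
#' `1e6 / population`.
#'
#' @param excess an [excess_deaths()]-style tibble (columns `excess_annual`,
#'   `ci_lo`, `ci_hi`, optionally `se`).
#' @param population at-risk population (scalar or one per row).
#' @return The input with added columns `per_1m`, `per_1m_lo`, `per_1m_hi`.
#' @export
per_capita <- function(excess, population) {
  if (any(population <= 0)) abort("population must be positive.")
  f <- 1e6 / population
  dplyr::mutate(
    excess,
    per_1m = .data$excess_annual * f,
    per_1m_lo = .data$ci_lo * f,
    per_1m_hi = .data$ci_hi * f
  )
}

#' Stratified excess-death report
#'
#' Applies [excess_deaths()] to one fit per stratum (age groups, sexes,
#' regions, metro status, ...) and stacks the results into a tidy table,
#' adding an aggregate row per component whose point estimate is the sum of
#' the stratum estimates and whose variance is the sum of their variances
#' (the fits are independent). When `populations` is supplied (named by
#' stratum), per-million rates are appended, with the aggregate denominator
#' being the summed population.
#'
#' Note that, as in region-restricted analyses generally, aggregates of
#' strata fitted on restricted panels need not reproduce a pooled national
#' fit.
#'
#' @param fits named list of [ppml_fit()] objects, one per stratum.
#' @param populations optional named numeric, at-risk population per stratum.
#' @param aggregate_label scope label for the summed row (default "all").
#' @param component components to report.
#' @param conf_level confidence level.
#' @return A tidy tibble: `scope`, `component`, `excess_annual`, `se`,
#'   `ci_lo`, `ci_hi` (and per-million columns when populations are given).
#' @export
stratified_report <- function(fits, populations = NULL,
                              aggregate_label = "all",
                              component = c("combined", "heat", "cold"),
                              conf_level = 0.95) {
  if (is.null(names(fits)) || any(names(fits) == "")) {
    abort("`fits` must be a fully named list (one fit per stratum).")
  }
  component <- match.arg(component, several.ok = TRUE)
  per_stratum <- purrr::imap(fits, function(f, nm) {
    excess_deaths(f, component = component, conf_level = conf_level) %>%
      dplyr::mutate(scope = nm, .before = 1)
  }) %>% dplyr::bind_rows()
  agg <- per_stratum %>%
    dplyr::group_by(.data$component) %>%
    dplyr::summarise(
      excess_annual = sum(.data$excess_annual),
      se = sqrt(sum(.data$se^2)),
      .groups = "drop"
    ) %>%
    dplyr::mutate(scope = aggregate_label, .before = 1)
  ci <- normal_ci(agg$excess_annual, agg$se, conf_level)
  agg$ci_lo <- ci$lo
  agg$ci_hi <- ci$hi
  out <- dplyr::bind_rows(per_stratum, agg) %>%
    dplyr::select(
      "scope", "component", "excess_annual", "se", "ci_lo", "ci_hi"
    )
  if (!is.null(populations)) {
    missing <- setdiff(names(fits), names(populations))
    if (length(missing) > 0) {
      abort(sprintf(
        "populations missing for strata: %s", paste(missing, collapse = ", ")
      ))
    }
    pops <- c(populations[names(fits)],
      setNames(sum(populations[names(fits)]), aggregate_label)
    )
    out <- per_capita(out, unname(pops[out$scope]))
  }
  out
}
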