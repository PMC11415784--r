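# Independent oracles used across test files. These deliberately avoid the
# package's own code paths: explicit dummy matrices plus a generic
# optimizer for the fixed-effects Poisson pseudo-likelihood, day-by-day
# loops for exposure counting, and type-7 percentile interpolation written
# out by hand.

# a small random county-month panel with Poisson deaths
small_panel <- function(seed, n_counties = 5, n_months = 24,
                        beta_hot = 0.02, beta_cold = 0.03) {
  set.seed(seed)
  grid <- expand.grid(
    county_id = seq_len(n_counties),
    month_index = seq_len(n_months)
  )
  grid$year <- 2000L + (grid$month_index - 1L) %/% 12L
  grid$month <- 1L + (grid$month_index - 1L) %% 12L
  grid$population <- rep(
    round(runif(n_counties, 5e4, 5e5)), times = n_months
  )
  grid$n_hot_days <- rpois(nrow(grid), 2)
  grid$n_cold_days <- rpois(nrow(grid), 2)
  cfe <- rnorm(n_counties, 0, 0.2)
  mfe <- rnorm(12, 0, 0.1)
  yfe <- rnorm(length(unique(grid$year)), 0, 0.05)
  eta <- log(grid$population / 1e5) + log(60) +
    cfe[grid$county_id] + mfe[grid$month] +
    yfe[match(grid$year, sort(unique(grid$year)))] +
    beta_hot * grid$n_hot_days + beta_cold * grid$n_cold_days
  grid$deaths <- rpois(nrow(grid), exp(eta))
  grid$rate <- 1e5 * grid$deaths / grid$population
  tibble::as_tibble(grid[order(grid$county_id, grid$year, grid$month), ])
}

# explicit-dummy design matrix for county + month + year fixed effects
oracle_design <- function(panel, exposure) {
  fe_terms <- c("county_id", "month", "year")
  fe_terms <- fe_terms[vapply(
    fe_terms, function(f) length(unique(panel[[f]])) > 1, TRUE
  )]
  f <- stats::as.formula(paste(
    "~", paste(c(exposure, paste0("factor(", fe_terms, ")")), collapse = " + ")
  ))
  stats::model.matrix(f, data = panel)
}

# maximize the weighted Poisson pseudo-likelihood over all parameters with
# a generic quasi-Newton optimizer; returns named coefficient vector
oracle_ppml <- function(panel, exposure = c("n_hot_days", "n_cold_days"),
                        outcome = c("rate", "count")) {
  outcome <- match.arg(outcome)
  X <- oracle_design(panel, exposure)
  if (outcome == "rate") {
    y <- panel$rate
    w <- panel$population
    o <- rep(0, nrow(X))
  } else {
    y <- panel$deaths
    w <- rep(1, nrow(X))
    o <- log(panel$population / 1e5)
  }
  nll <- function(th) {
    eta <- o + drop(X %*% th)
    -sum(w * (y * eta - exp(eta)))
  }
  grad <- function(th) {
    mu <- exp(o + drop(X %*% th))
    -drop(crossprod(X, w * (y - mu)))
  }
  start <- c(log(stats::weighted.mean(y, w) + 1e-8), rep(0, ncol(X) - 1))
  opt <- stats::optim(start, nll, grad,
    method = "BFGS",
    control = list(maxit = 5000, reltol = 1e-16)
  )
  # polish with a few Newton steps for tight agreement
  th <- opt$par
  for (i in 1:25) {
    mu <- exp(o + drop(X %*% th))
    g <- drop(crossprod(X, w * (y - mu)))
    H <- crossprod(X, (w * mu) * X)
    step <- solve(H, g)
    th <- th + step
    if (max(abs(step)) < 1e-13) break
  }
  stats::setNames(th, colnames(X))
}

oracle_predict_mu <- function(panel, theta, exposure) {
  X <- oracle_design(panel, exposure)
  unname(exp(drop(X %*% theta[colnames(X)])) * panel$population / 1e5)
}

# day-by-day loop recount of monthly extreme-day flags
brute_force_counts <- function(daily, thresholds) {
  out <- list()
  for (i in seq_len(nrow(daily))) {
    row <- daily[i, ]
    th <- thresholds[thresholds$county_id == row$county_id, ]
    key <- paste(
      row$county_id, format(row$date, "%Y"), format(row$date, "%m")
    )
    if (is.null(out[[key]])) out[[key]] <- c(hot = 0, cold = 0)
    if (row$temp_C > th$hot_threshold_C) out[[key]]["hot"] <- out[[key]]["hot"] + 1
    if (row$temp_C < th$cold_threshold_C) out[[key]]["cold"] <- out[[key]]["cold"] + 1
  }
  keys <- do.call(rbind, strsplit(names(out), " "))
  tibble::tibble(
    county_id = as.integer(keys[, 1]),
    year = as.integer(keys[, 2]),
    month = as.integer(keys[, 3]),
    n_hot_days = vapply(out, `[[`, 0, "hot"),
    n_cold_days = vapply(out, `[[`, 0, "cold")
  ) |> dplyr::arrange(county_id, year, month)
}

# type-7 percentile by hand: sort, index, interpolate
sort_index_percentile <- function(x, p) {
  xs <- sort(x)
  h <- (length(xs) - 1) * p + 1
  lo <- floor(h)
  xs[lo] + (h - lo) * (xs[min(lo + 1, length(xs))] - xs[lo])
}

# a quick small-scale synthetic configuration for structural tests
small_config <- function(seed = 1, n_gcms = 3, ...) {
  synthetic_config(
    n_counties = 16, grid_shape = c(4, 4),
    baseline_years = 1991:1992, current_years = 2008:2009,
    projection_years = 2046:2047, n_gcms = n_gcms,
    pop_range = c(2e5, 2e6),
    seed = seed, ...
  )
}

# fabricate a ppml-fit-shaped object whose linear predictor and
# coefficients are exact, for truth-injection tests
fake_rate_fit <- function(panel, beta_hot, beta_cold, vcov = diag(0, 2)) {
  eta <- log(1e5 * panel$expected_deaths / panel$population)
  beta <- c(n_hot_days = beta_hot, n_cold_days = beta_cold)
  dimnames(vcov) <- list(names(beta), names(beta))
  structure(
    list(
      coefficients = beta, vcov = vcov, se = sqrt(diag(vcov)),
      exposure = c("n_hot_days", "n_cold_days"),
      exposure_cols = c("n_hot_days", "n_cold_days"),
      exposure_spline = FALSE, covariates = NULL,
      fe = c("county_id", "month", "year"), outcome = "rate",
      rate_col = "rate", deaths_col = "deaths", pop_col = "population",
      data = panel, eta = eta, offset = rep(0, nrow(panel)),
      fitted_mu = exp(eta), weights = panel$population,
      fe_effects = NULL, dropped = character(), n_na_dropped = 0L
    ),
    class = "tempmort_ppml"
  )
}
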