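test_that("expected deaths obey the arithmetic and oracle predictions", {
  # hand case: rate 50 per 100k, population 200,000 -> 100 deaths
  panel <- tibble::tibble(
    county_id = 1L, year = 2008L, month = 1L,
    rate = 50, population = 2e5, expected_deaths = 100,
    n_hot_days = 0, n_cold_days = 0, deaths = 100
  )
  fit <- fake_rate_fit(panel, 0.001, 0.002)
  pred <- predict_expected_deaths(fit)
  expect_equal(pred$mu_hat, 100)

  # full oracle comparison on a small instance
  pnl <- small_panel(seed = 42)
  f <- ppml_fit(pnl)
  theta <- oracle_ppml(pnl)
  mu_pkg <- predict_expected_deaths(f)$mu_hat
  mu_oracle <- oracle_predict_mu(pnl, theta, c("n_hot_days", "n_cold_days"))
  expect_equal(mu_pkg, mu_oracle, tolerance = 1e-6)
})

test_that("rebuilt linear predictors match stored ones and reject unseen counties", {
  study <- simulate_study(small_config(seed = 6))
  panel <- dplyr::filter(study$mortality, age_group == "older")
  fit <- ppml_fit(panel, covariates = "covariate1")
  pred_stored <- predict_expected_deaths(fit)
  pred_rebuilt <- predict_expected_deaths(fit, fit$data)
  expect_equal(pred_rebuilt$mu_hat, pred_stored$mu_hat, tolerance = 1e-7)
  bad <- dplyr::mutate(fit$data[1:3, ], county_id = 999L)
  expect_error(predict_expected_deaths(fit, bad), "absent from fit")
})

test_that("null coefficients and zero exposure give zero excess", {
  pnl <- small_panel(seed = 2)
  pnl$expected_deaths <- pnl$deaths + 0.5
  pnl$rate <- 1e5 * pnl$expected_deaths / pnl$population
  fit0 <- fake_rate_fit(pnl, 0, 0, vcov = diag(1e-6, 2))
  ex0 <- excess_deaths(fit0)
  expect_equal(ex0$excess_annual, rep(0, 3))
  expect_equal(ex0$ci_lo + ex0$ci_hi, rep(0, 3), tolerance = 1e-10)

  # no heat days: heat excess identically zero whatever the coefficient
  pnl2 <- dplyr::mutate(pnl, n_hot_days = 0)
  fit2 <- fake_rate_fit(pnl2, 0.3, 0.001)
  expect_equal(
    excess_deaths(fit2, component = "heat")$excess_annual, 0
  )
})

test_that("excess at true parameters equals the closed-form truth", {
  study <- simulate_study(small_config(seed = 14))
  for (grp in c("older", "younger")) {
    pan <- study$truth$expected_panel |>
      dplyr::filter(age_group == grp) |>
      dplyr::inner_join(
        dplyr::distinct(
          study$mortality[study$mortality$age_group == grp, ],
          county_id, population
        ),
        by = "county_id"
      )
    fit <- fake_rate_fit(
      pan,
      study$config$beta_heat[[grp]], study$config$beta_cold[[grp]]
    )
    ex <- excess_deaths(fit)
    for (cmp in c("combined", "heat", "cold")) {
      expect_equal(
        ex$excess_annual[ex$component == cmp],
        truth_excess(study$truth, cmp, grp),
        tolerance = 1e-10
      )
    }
  }
})

test_that("heat plus cold equals combined exactly and CI width scales with SE", {
  pnl <- small_panel(seed = 3)
  fit <- ppml_fit(pnl)
  ex <- excess_deaths(fit)
  expect_equal(
    ex$excess_annual[ex$component == "combined"],
    sum(ex$excess_annual[ex$component %in% c("heat", "cold")]),
    tolerance = 1e-12
  )
  # quadrupling the coefficient covariance doubles the delta-method width
  fit4 <- fit
  fit4$vcov <- fit$vcov * 4
  ex4 <- excess_deaths(fit4)
  expect_equal(
    ex4$ci_hi - ex4$ci_lo, 2 * (ex$ci_hi - ex$ci_lo),
    tolerance = 1e-10
  )
  # monotonicity: inflating every hot-day count raises heat excess
  stopifnot(fit$coefficients["n_hot_days"] > 0)
  more <- dplyr::mutate(fit$data, n_hot_days = n_hot_days + 2)
  ex_more <- excess_deaths(fit, panel = more, component = "heat")
  expect_gt(ex_more$excess_annual, ex$excess_annual[ex$component == "heat"])
})

test_that("simulation CIs agree broadly with delta-method CIs", {
  pnl <- small_panel(seed = 4)
  fit <- ppml_fit(pnl)
  d <- excess_deaths(fit, component = "combined")
  s <- excess_deaths(fit,
    component = "combined", ci_method = "simulation",
    n_draws = 20000, seed = 99
  )
  expect_equal(s$excess_annual, d$excess_annual)
  expect_lt(abs(s$se - d$se) / d$se, 0.15)
})

test_that("per-capita rescaling matches the published arithmetic", {
  est <- tibble::tibble(
    component = "combined", excess_annual = 8248.6,
    se = NA_real_, ci_lo = 4242.6, ci_hi = 12254.6
  )
  pc <- per_capita(est, 233011300)
  expect_equal(round(pc$per_1m, 1), 35.4)
  expect_equal(round(pc$per_1m_lo, 1), 18.2)
  expect_equal(round(pc$per_1m_hi, 1), 52.6)
  # zero excess stays zero; doubling the population halves the rate
  zero <- per_capita(dplyr::mutate(est, excess_annual = 0), 1e6)
  expect_equal(zero$per_1m, 0)
  half <- per_capita(est, 2 * 233011300)
  expect_equal(half$per_1m, pc$per_1m / 2)
  expect_error(per_capita(est, 0), "positive")
})

test_that("stratified reports aggregate independent fits correctly", {
  study <- simulate_study(small_config(seed = 15))
  fits <- list(
    older = ppml_fit(dplyr::filter(study$mortality, age_group == "older")),
    younger = ppml_fit(dplyr::filter(study$mortality, age_group == "younger"))
  )
  pops <- c(
    older = sum(study$counties$pop_older),
    younger = sum(study$counties$pop_younger)
  )
  rep <- stratified_report(fits, populations = pops)
  for (cmp in c("heat", "cold", "combined")) {
    sub <- rep[rep$component == cmp, ]
    expect_equal(
      sub$excess_annual[sub$scope == "all"],
      sum(sub$excess_annual[sub$scope != "all"]),
      tolerance = 1e-10
    )
  }
  expect_true(all(c("per_1m", "per_1m_lo", "per_1m_hi") %in% names(rep)))
  # identical strata double the aggregate
  twin <- stratified_report(list(a = fits$older, b = fits$older))
  t_all <- twin[twin$scope == "all" & twin$component == "combined", ]
  t_one <- twin[twin$scope == "a" & twin$component == "combined", ]
  expect_equal(t_all$excess_annual, 2 * t_one$excess_annual)
  expect_error(stratified_report(list(fits$older)), "named")
})

test_that("region-restricted fits match region-restricted oracle fits", {
  study <- simulate_study(small_config(seed = 16))
  panel <- dplyr::filter(study$mortality, age_group == "older")
  for (reg in c("Northeast", "West")) {
    sub <- dplyr::filter(panel, region == reg)
    fit <- ppml_fit(sub)
    oracle <- oracle_ppml(sub)
    expect_equal(
      unname(fit$coefficients[c("n_hot_days", "n_cold_days")]),
      unname(oracle[c("n_hot_days", "n_cold_days")]),
      tolerance = 1e-6
    )
  }
})
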