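test_that("identity scenario reproduces current-period estimates exactly", {
  # strong planted effects keep every current-period component positive
  study <- simulate_study(small_config(
    seed = 20,
    beta_heat = c(older = log(1.01), younger = log(1.01)),
    beta_cold = c(older = log(1.01), younger = log(1.01))
  ))
  panel <- dplyr::filter(study$mortality, age_group == "older")
  fit <- ppml_fit(panel, covariates = "covariate1")
  current <- excess_deaths(fit)
  identity_exposure <- dplyr::mutate(study$exposure, gcm = 1L)
  identity_pop <- dplyr::distinct(panel, county_id, population)
  proj <- project_excess(fit, identity_exposure, identity_pop, "ssp2-4.5")
  for (cmp in c("combined", "heat", "cold")) {
    expect_equal(
      proj$summary$excess_annual[proj$summary$component == cmp],
      current$excess_annual[current$component == cmp],
      tolerance = 1e-12
    )
  }
  expect_equal(proj$summary$pct_change, rep(0, 3), tolerance = 1e-10)
  # a single GCM is its own ensemble mean
  expect_equal(proj$summary$gcm_min, proj$summary$gcm_max)
  expect_equal(
    proj$summary$excess_annual,
    proj$per_gcm$excess_annual[match(
      proj$summary$component, proj$per_gcm$component
    )]
  )
})

test_that("projection equals a brute-force per-county re-evaluation loop", {
  study <- simulate_study(small_config(seed = 22))
  panel <- dplyr::filter(study$mortality, age_group == "older")
  fit <- ppml_fit(panel)
  stacked <- gcm_exposure_panels(study$temps, study$thresholds, "rcp45")
  collapsed <- gcm_ensemble_exposure(stacked)$per_gcm
  pop <- study$pop_projection |>
    dplyr::filter(scenario == "ssp2-4.5", age_group == "older") |>
    dplyr::select(county_id, population)
  proj <- project_excess(fit, collapsed, pop, "ssp2-4.5")

  # independent loop: average the exposure-free log rate by county-month,
  # then accumulate mu * (1 - exp(-beta * X)) county by county, GCM by GCM
  bh <- fit$coefficients[["n_hot_days"]]
  bc <- fit$coefficients[["n_cold_days"]]
  base_log <- fit$eta -
    bh * fit$data$n_hot_days - bc * fit$data$n_cold_days
  base_tab <- stats::aggregate(
    base_log ~ county_id + month,
    data = cbind(fit$data[c("county_id", "month")], base_log), mean
  )
  total_heat <- setNames(numeric(0), character(0))
  for (g in unique(collapsed$gcm)) {
    acc <- 0
    sub <- collapsed[collapsed$gcm == g, ]
    for (i in seq_len(nrow(sub))) {
      b <- base_tab$base_log[
        base_tab$county_id == sub$county_id[i] & base_tab$month == sub$month[i]
      ]
      p <- pop$population[pop$county_id == sub$county_id[i]]
      mu <- exp(b + bh * sub$n_hot_days[i] + bc * sub$n_cold_days[i]) * p / 1e5
      acc <- acc + mu * (1 - exp(-bh * sub$n_hot_days[i]))
    }
    total_heat[as.character(g)] <- acc
  }
  expect_equal(
    sort(unname(total_heat)),
    sort(proj$per_gcm$excess_annual[proj$per_gcm$component == "heat"]),
    tolerance = 1e-10
  )
  hm <- proj$summary[proj$summary$component == "heat", ]
  expect_equal(hm$excess_annual, mean(total_heat), tolerance = 1e-10)
  # ensemble mean lies inside the per-GCM range
  expect_true(all(
    proj$summary$excess_annual >= proj$summary$gcm_min - 1e-9 &
      proj$summary$excess_annual <= proj$summary$gcm_max + 1e-9
  ))
})

test_that("invalid scenarios and populations are rejected", {
  study <- simulate_study(small_config(seed = 23))
  panel <- dplyr::filter(study$mortality, age_group == "older")
  fit <- ppml_fit(panel)
  expo <- dplyr::mutate(study$exposure, gcm = 1L)
  pop <- dplyr::distinct(panel, county_id, population)
  expect_error(
    project_excess(fit, expo, pop, "ssp3-7.0"),
    "arg"
  )
  expect_error(
    project_excess(
      fit, expo, dplyr::mutate(pop, population = -population), "ssp2-4.5"
    ),
    "positive"
  )
  expect_error(
    project_excess(
      fit, dplyr::mutate(expo, county_id = county_id + 500L), pop, "ssp2-4.5"
    ),
    "absent from fit"
  )
})

test_that("percent change matches published ratio arithmetic", {
  expect_equal(round(percent_change(8248.6, 19348.7)$pct_change, 1), 134.6)
  expect_equal(round(percent_change(8248.6, 26574.0)$pct_change, 1), 222.2)
  expect_equal(round(percent_change(35.4, 62.5)$pct_change, 1), 76.6)
  expect_equal(percent_change(10, 10)$pct_change, 0)
  expect_error(percent_change(0, 5), "positive")
  # delta CI collapses when projected tracks current one-for-one
  pc <- percent_change(100, 100,
    vcov = matrix(4), grad_current = 1, grad_projected = 1
  )
  expect_equal(pc$ci_lo, pc$ci_hi)
})

test_that("stronger warming weakly raises heat excess and lowers cold excess", {
  study <- simulate_study(small_config(
    seed = 24,
    beta_heat = c(older = log(1.01), younger = log(1.01)),
    beta_cold = c(older = log(1.01), younger = log(1.01))
  ))
  panel <- dplyr::filter(study$mortality, age_group == "older")
  fit <- ppml_fit(panel)
  stopifnot(
    fit$coefficients[["n_hot_days"]] > 0,
    fit$coefficients[["n_cold_days"]] > 0
  )
  pop <- dplyr::distinct(panel, county_id, population)
  proj_daily <- dplyr::filter(study$temps$daily, period == "projection")
  prev_heat <- -Inf
  prev_cold <- Inf
  for (shift in c(0, 1.5, 3)) {
    expo <- count_extreme_days(
      dplyr::mutate(proj_daily, temp_C = temp_C + shift), study$thresholds
    ) |> dplyr::mutate(gcm = 1L)
    expo_cm <- gcm_ensemble_exposure(expo)$per_gcm
    proj <- project_excess(fit, expo_cm, pop, "ssp2-4.5")
    heat <- proj$summary$excess_annual[proj$summary$component == "heat"]
    cold <- proj$summary$excess_annual[proj$summary$component == "cold"]
    expect_gte(heat, prev_heat - 1e-9)
    expect_lte(cold, prev_cold + 1e-9)
    prev_heat <- heat
    prev_cold <- cold
  }
})

test_that("combining stratum projections adds estimates and per-GCM values", {
  study <- simulate_study(small_config(seed = 25))
  fits <- list(
    older = ppml_fit(dplyr::filter(study$mortality, age_group == "older")),
    younger = ppml_fit(dplyr::filter(study$mortality, age_group == "younger"))
  )
  expo <- gcm_ensemble_exposure(
    gcm_exposure_panels(study$temps, study$thresholds, "rcp45")
  )$per_gcm
  projs <- lapply(names(fits), function(grp) {
    pop <- study$pop_projection |>
      dplyr::filter(scenario == "ssp2-4.5", age_group == grp) |>
      dplyr::select(county_id, population)
    project_excess(fits[[grp]], expo, pop, "ssp2-4.5")
  })
  names(projs) <- names(fits)
  comb <- combine_projections(projs)
  idx <- match(comb$summary$component, projs$older$summary$component)
  expect_equal(
    comb$summary$excess_annual,
    projs$older$summary$excess_annual[idx] +
      projs$younger$summary$excess_annual[idx]
  )
  p <- autoplot(projs$older)
  expect_s3_class(p, "ggplot")
})
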