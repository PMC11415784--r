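make_daily <- function(temps, county = 1L, start = "2008-01-01") {
  tibble::tibble(
    county_id = county,
    date = seq(as.Date(start), by = "day", length.out = length(temps)),
    temp_C = temps
  )
}

test_that("thresholds match a sort-and-interpolate percentile oracle", {
  set.seed(42)
  x <- runif(1000, 0, 40)
  daily <- make_daily(x)
  th <- compute_thresholds(daily)
  expect_equal(th$hot_threshold_C, sort_index_percentile(x, 0.975))
  expect_equal(th$cold_threshold_C, sort_index_percentile(x, 0.025))
  expect_lt(abs(th$hot_threshold_C - 39), 0.8)
  expect_lt(abs(th$cold_threshold_C - 1), 0.8)
  # thresholds always lie inside the observed range
  expect_gt(th$hot_threshold_C, min(x))
  expect_lt(th$hot_threshold_C, max(x))
})

test_that("degenerate and invalid inputs are rejected", {
  expect_error(
    compute_thresholds(make_daily(rep(20, 200))),
    "degenerate"
  )
  expect_error(
    compute_thresholds(make_daily(runif(50))),
    "fewer than"
  )
  expect_error(
    compute_thresholds(make_daily(c(runif(199), NaN))),
    "non-finite"
  )
})

test_that("stricter percentile pairs are never interior to the default pair", {
  set.seed(7)
  for (i in 1:5) {
    daily <- make_daily(rnorm(800, 15, 8))
    th_default <- compute_thresholds(daily)
    th_sens <- compute_thresholds(daily, percentiles = c(99, 1))
    expect_gte(th_sens$hot_threshold_C, th_default$hot_threshold_C)
    expect_lte(th_sens$cold_threshold_C, th_default$cold_threshold_C)
  }
})

test_that("extreme-day counting uses strict inequalities and exact counts", {
  th <- tibble::tibble(
    county_id = 1L, hot_threshold_C = 30, cold_threshold_C = 0
  )
  # 31-day January: 4 days above the hot threshold, one exactly at it
  temps <- rep(15, 31)
  temps[c(3, 10, 20, 25)] <- 35
  temps[5] <- 30 # tie: not counted
  panel <- count_extreme_days(make_daily(temps), th)
  expect_identical(panel$n_hot_days, 4L)
  expect_identical(panel$n_cold_days, 0L)

  # all interior days count zero
  interior <- count_extreme_days(make_daily(rep(10, 60)), th)
  expect_true(all(interior$n_hot_days == 0 & interior$n_cold_days == 0))

  expect_error(
    count_extreme_days(
      make_daily(rep(10, 30), county = 2L), th
    ),
    "do not cover"
  )
})

test_that("monthly counts match a brute-force day-by-day recount", {
  cfg <- small_config(seed = 21)
  temps <- simulate_temperatures(cfg)
  baseline <- dplyr::filter(temps$daily, period == "baseline")
  th <- compute_thresholds(baseline)
  sub <- dplyr::filter(
    temps$daily, period == "current", county_id <= 4
  )
  fast <- count_extreme_days(sub, th)
  slow <- brute_force_counts(sub, th)
  expect_equal(
    as.data.frame(fast[c("county_id", "year", "month")]),
    as.data.frame(slow[c("county_id", "year", "month")])
  )
  expect_equal(fast$n_hot_days, as.integer(slow$n_hot_days))
  expect_equal(fast$n_cold_days, as.integer(slow$n_cold_days))
  # counting conservation: monthly counts sum to the whole-series flag count
  joined <- dplyr::inner_join(sub, th, by = "county_id")
  expect_identical(
    sum(fast$n_hot_days),
    sum(joined$temp_C > joined$hot_threshold_C)
  )
  # a uniform +3 C shift flags exactly the days above (threshold - 3)
  shifted <- dplyr::mutate(sub, temp_C = temp_C + 3)
  expect_identical(
    sum(count_extreme_days(shifted, th)$n_hot_days),
    sum(joined$temp_C > joined$hot_threshold_C - 3)
  )
})

test_that("warming shifts move counts monotonically", {
  cfg <- small_config(seed = 33)
  temps <- simulate_temperatures(cfg)
  th <- compute_thresholds(
    dplyr::filter(temps$daily, period == "baseline")
  )
  proj <- dplyr::filter(temps$daily, period == "projection")
  prev <- NULL
  for (shift in c(0, 1.5, 3)) {
    cnt <- count_extreme_days(
      dplyr::mutate(proj, temp_C = temp_C + shift), th
    )
    if (!is.null(prev)) {
      expect_true(all(cnt$n_hot_days >= prev$n_hot_days))
      expect_true(all(cnt$n_cold_days <= prev$n_cold_days))
    }
    prev <- cnt
  }
})

test_that("heat index reproduces the published regression regimes", {
  # below the 80 F regime the simple average stays within 1 C of T
  expect_lt(abs(heat_index(26, 50) - 26), 1)
  # 90 F at 70% humidity is the canonical 105 F chart cell
  hi_f <- heat_index(32.2222, 70) * 9 / 5 + 32
  expect_lt(abs(hi_f - 105), 1)
  # dry-air adjustment branch stays finite and below the humid value
  expect_true(is.finite(heat_index(40, 0)))
  expect_lt(heat_index(40, 0), heat_index(40, 90))
  # monotone in humidity in the hot regime
  hs <- heat_index(rep(35, 5), c(20, 40, 60, 80, 100))
  expect_true(all(diff(hs) > 0))
  expect_error(heat_index(30, 120), "humidity")
})

test_that("ensemble averaging equals a brute-force loop over GCMs", {
  cfg <- small_config(seed = 13, n_gcms = 20)
  temps <- simulate_temperatures(cfg)
  th <- compute_thresholds(
    dplyr::filter(temps$daily, period == "baseline")
  )
  stacked <- gcm_exposure_panels(temps, th, "rcp45")
  ens <- gcm_ensemble_exposure(stacked)
  # loop oracle: average by hand over years within GCM, then over GCMs
  manual <- list()
  for (g in unique(stacked$gcm)) {
    sub <- stacked[stacked$gcm == g, ]
    agg <- stats::aggregate(
      cbind(n_hot_days, n_cold_days) ~ county_id + month, sub, mean
    )
    agg$gcm <- g
    manual[[g]] <- agg
  }
  manual <- do.call(rbind, manual)
  manual_ens <- stats::aggregate(
    cbind(n_hot_days, n_cold_days) ~ county_id + month, manual, mean
  )
  key <- order(manual_ens$county_id, manual_ens$month)
  manual_ens <- manual_ens[key, ]
  expect_equal(ens$ensemble$n_hot_days, manual_ens$n_hot_days)
  expect_equal(ens$ensemble$n_cold_days, manual_ens$n_cold_days)

  # identical panels: the ensemble mean is any single panel
  one <- dplyr::mutate(dplyr::filter(stacked, gcm == 1), gcm = NULL)
  dup <- dplyr::bind_rows(
    dplyr::mutate(one, gcm = 1), dplyr::mutate(one, gcm = 2)
  )
  ens2 <- gcm_ensemble_exposure(dup)
  single <- gcm_ensemble_exposure(dplyr::mutate(one, gcm = 1))
  expect_equal(ens2$ensemble, single$ensemble)

  # two GCMs with July means 10 and 20 average to 15
  jul <- tibble::tibble(
    gcm = c(1, 2), county_id = 1L, year = 2050L, month = 7L,
    n_hot_days = c(10, 20), n_cold_days = 0
  )
  expect_equal(
    gcm_ensemble_exposure(jul)$ensemble$n_hot_days, 15
  )
})

test_that("centroid aggregation averages series within county", {
  ct <- tibble::tibble(
    county_id = 1L, centroid_id = rep(1:3, each = 2),
    date = rep(as.Date("2008-01-01") + 0:1, 3),
    temp_C = c(10, 20, 20, 30, 30, 40)
  )
  agg <- aggregate_centroids(ct)
  expect_equal(agg$temp_C, c(20, 30))
})
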