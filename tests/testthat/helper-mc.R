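# Memoised Monte Carlo runs shared between the property and acceptance
# tests (each is computed once per test session).

.mc_cache <- new.env(parent = emptyenv())

# 50-replicate parameter-recovery run at the default study scale with the
# planted per-extreme-day effects; returns one row per seed x age group x term
mc_recovery <- function(n_seeds = 50) {
  key <- paste0("recovery", n_seeds)
  if (!is.null(.mc_cache[[key]])) {
    return(.mc_cache[[key]])
  }
  rows <- list()
  for (s in seq_len(n_seeds)) {
    study <- simulate_study(synthetic_config(seed = s))
    for (grp in c("older", "younger")) {
      fit <- ppml_fit(
        dplyr::filter(study$mortality, age_group == grp),
        covariates = "covariate1"
      )
      pc <- percent_change_per_day(fit)
      truth_pct <- 100 * expm1(c(
        study$config$beta_heat[[grp]], study$config$beta_cold[[grp]]
      ))
      rows[[length(rows) + 1]] <- dplyr::mutate(
        pc,
        seed = s, age_group = grp, truth = truth_pct,
        covered = ci_lo <= truth_pct & truth_pct <= ci_hi
      )
    }
  }
  .mc_cache[[key]] <- dplyr::bind_rows(rows)
  .mc_cache[[key]]
}

# 50-replicate null run (no planted effects): estimated combined excess
# deaths and the coefficient CIs, older-adult stratum
mc_null <- function(n_seeds = 50) {
  key <- paste0("null", n_seeds)
  if (!is.null(.mc_cache[[key]])) {
    return(.mc_cache[[key]])
  }
  zero <- c(older = 0, younger = 0)
  rows <- list()
  for (s in seq_len(n_seeds)) {
    study <- simulate_study(synthetic_config(
      beta_heat = zero, beta_cold = zero, seed = 1000 + s
    ))
    fit <- ppml_fit(
      dplyr::filter(study$mortality, age_group == "older"),
      covariates = "covariate1"
    )
    ex <- excess_deaths(fit, component = "combined")
    pc <- percent_change_per_day(fit)
    rows[[length(rows) + 1]] <- tibble::tibble(
      seed = s,
      excess = ex$excess_annual,
      excess_se = ex$se,
      ci_covers_zero = all(pc$ci_lo <= 0 & pc$ci_hi >= 0)
    )
  }
  .mc_cache[[key]] <- dplyr::bind_rows(rows)
  .mc_cache[[key]]
}
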