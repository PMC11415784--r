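#' Tidy a PPML fit
#'
#' @param x a [ppml_fit()] object.
#' @param conf_level confidence level for the intervals.
#' @param ... unused.
#' @return A tibble with one row per explicit coefficient: `term`,
#'   `estimate`, `std.error` (robust), `statistic`, `p.value`, `conf.low`,
#'   `conf.high`, and `pct_change` (the percent change in the monthly rate
#'   per unit of the term).
#' @method tidy tempmort_ppml
#' @export
tidy.tempmort_ppml <- function(x, conf_level = 0.95, ...) {
  b <- x$coefficients
  se <- x$se
  ci <- normal_ci(b, se, conf_level)
  tibble::tibble(
    term = names(b),
    estimate = unname(b),
    std.error = unname(se),
    statistic = unname(b / se),
    p.value = unname(2 * pnorm(-abs(b / se))),
    conf.low = unname(ci$lo),
    conf.high = unname(ci$hi),
    pct_change = unname(100 * expm1(b))
  )
}

#' One-row summary of a PPML fit
#'
#' @param x a [ppml_fit()] object.
#' @param ... unused.
#' @return A one-row tibble: `nobs`, `k_explicit`, `k_absorbed`,
#'   `deviance`, `logpl`, `bic`, `niter`, `converged`, `n_dropped_separation`,
#'   `n_dropped_na`.
#' @method glance tempmort_ppml
#' @export
glance.tempmort_ppml <- function(x, ...) {
  tibble::tibble(
    nobs = x$nobs,
    k_explicit = x$k_explicit,
    k_absorbed = x$k_absorbed,
    deviance = x$deviance,
    logpl = x$logpl,
    bic = x$bic,
    niter = x$niter,
    converged = x$converged,
    n_dropped_separation = length(x$dropped),
    n_dropped_na = x$n_na_dropped
  )
}

#' @export
print.tempmort_ppml <- function(x, ...) {
  cat("<tempmort_ppml> Poisson pseudo-ML fit with absorbed fixed effects\n")
  cat(sprintf(
    "  n = %d, outcome mode = %s, absorbed: %s (%d levels)\n",
    x$nobs, x$outcome, paste(x$fe, collapse = " + "), x$k_absorbed
  ))
  print(percent_change_per_day(x), n = Inf)
  invisible(x)
}

#' Forest plot of exposure effects on the percent-change scale
#'
#' @param object a [ppml_fit()] object.
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot tempmort_ppml
#' @export
autoplot.tempmort_ppml <- function(object, ...) {
  pc <- percent_change_per_day(object)
  ggplot2::ggplot(pc, ggplot2::aes(
    x = .data$pct_change, y = .data$term,
    xmin = .data$ci_lo, xmax = .data$ci_hi
  )) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange() +
    ggplot2::labs(
      x = "% change in monthly mortality rate per additional extreme day",
      y = NULL
    ) +
    ggplot2::theme_minimal()
}
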