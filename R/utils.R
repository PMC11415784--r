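#' Check that a data frame contains required columns
#'
#' @param df a data frame
#' @param cols character vector of required column names
#' @param what label used in the error message
#' @noRd
check_columns <- function(df, cols, what = "input") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf(
      "%s is missing required column(s): %s",
      what, paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}

#' Weighted group means, repeated for each observation
#'
#' @param x numeric vector
#' @param g grouping vector (factor-coercible)
#' @param w non-negative weights
#' @noRd
group_wmean <- function(x, g, w) {
  g <- as.integer(g)
  num <- rowsum(x * w, g, reorder = TRUE)
  den <- rowsum(w, g, reorder = TRUE)
  (num / den)[match(g, sort(unique(g)))]
}

#' Number of days in a civil-calendar month
#' @noRd
days_in_month <- function(year, month) {
  first <- as.Date(sprintf("%d-%02d-01", year, month))
  nxt <- ifelse(month == 12,
    sprintf("%d-01-01", year + 1),
    sprintf("%d-%02d-01", year, month + 1)
  )
  as.integer(as.Date(nxt) - first)
}

#' Two-sided normal confidence limits
#' @noRd
normal_ci <- function(est, se, conf_level = 0.95) {
  z <- qnorm(1 - (1 - conf_level) / 2)
  list(lo = est - z * se, hi = est + z * se)
}
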