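#' Poisson pseudo-maximum-likelihood regression with absorbed fixed effects
#'
#' Estimates the association between monthly extreme-temperature-day counts
#' and mortality by Poisson pseudo-maximum-likelihood (PPML), absorbing
#' county, month, and year fixed effects by iterated weighted within-group
#' demeaning rather than explicit dummies. Because only the Poisson score
#' equations are used, the outcome may be a non-integer rate; robust
#' (sandwich) standard errors make inference valid under overdispersion.
#'
#' Two outcome modes are supported. In `"rate"` mode (default) the outcome
#' is the monthly mortality rate per 100,000 and observations carry analytic
#' weights equal to population, so the score equations match those of the
#' corresponding count model. In `"count"` mode the outcome is the death
#' count with `log(population / 1e5)` as offset.
#'
#' Fitting is iteratively reweighted least squares: at each step the working
#' response and regressors are residualised against all absorbed
#' fixed-effect sets by alternating weighted demeaning (to tolerance
#' `demean_tol`), followed by weighted least squares on the demeaned system;
#' convergence is declared when the relative deviance change falls below
#' `dev_tol`. Fixed-effect groups whose outcome is identically zero are
#' perfectly separated, dropped, and logged.
#'
#' @param panel data frame with the outcome, exposure, fixed-effect, and
#'   covariate columns.
#' @param exposure character vector of exposure columns (default monthly
#'   extreme heat and cold day counts).
#' @param fe character vector of columns to absorb as fixed effects.
#' @param covariates character vector of smooth covariate columns, each
#'   entered as a restricted cubic spline.
#' @param spline_knots knots per covariate spline (default 4).
#' @param exposure_spline if `TRUE`, replace each exposure column by a
#'   restricted cubic spline of itself (specification-comparison variant;
#'   see [bic_compare()]).
#' @param outcome `"rate"` or `"count"`.
#' @param rate_col,deaths_col,pop_col column names used by the two modes.
#' @param cluster optional column name for cluster-robust standard errors;
#'   `NULL` (default) gives heteroskedasticity-robust errors.
#' @param demean_tol,dev_tol,max_iter numerical controls.
#'
#' @return An object of class `tempmort_ppml`: coefficients, robust
#'   covariance, deviance, log-pseudolikelihood, BIC, the fitting panel with
#'   fitted means, recovered fixed effects, and a dropped-observation log.
#'   Supports [tidy()], [glance()], `print()`, [autoplot()],
#'   [percent_change_per_day()], and the attribution and projection
#'   functions.
#' @export
ppml_fit <- function(panel,
                     exposure = c("n_hot_days", "n_cold_days"),
                     fe = c("county_id", "month", "year"),
                     covariates = NULL,
                     spline_knots = 4,
                     exposure_spline = FALSE,
                     outcome = c("rate", "count"),
                     rate_col = "rate", deaths_col = "deaths",
                     pop_col = "population",
                     cluster = NULL,
                     demean_tol = 1e-10, dev_tol = 1e-9, max_iter = 100L) {
  outcome <- match.arg(outcome)
  if (length(exposure) == 0) abort("at least one exposure term is required.")
  ycol <- if (outcome == "rate") rate_col else deaths_col
  used <- unique(c(ycol, pop_col, exposure, fe, covariates, cluster))
  check_columns(panel, used, "panel")
  panel <- tibble::as_tibble(panel)

  complete <- stats::complete.cases(panel[used])
  n_na <- sum(!complete)
  data <- panel[complete, , drop = FALSE]

  # design matrix: exposure (possibly splined) + covariate splines
  bases <- list()
  xs <- list()
  for (v in exposure) {
    if (exposure_spline) {
      b <- rcs_basis(data[[v]], n_knots = spline_knots)
      colnames(b) <- paste0(v, "_", colnames(b))
      bases[[v]] <- b
      xs[[v]] <- unclass(b)
    } else {
      xs[[v]] <- matrix(data[[v]], dimnames = list(NULL, v))
    }
  }
  for (v in covariates %||% character()) {
    b <- rcs_basis(data[[v]], n_knots = spline_knots)
    colnames(b) <- paste0(v, "_", colnames(b))
    bases[[v]] <- b
    xs[[v]] <- unclass(b)
  }
  X <- do.call(cbind, xs)
  exposure_cols <- if (exposure_spline) {
    unlist(lapply(exposure, function(v) paste0(v, "_", colnames(bases[[v]]))))
  } else {
    exposure
  }

  if (outcome == "rate") {
    y <- data[[rate_col]]
    w <- as.numeric(data[[pop_col]])
    o <- rep(0, nrow(data))
  } else {
    y <- as.numeric(data[[deaths_col]])
    w <- rep(1, nrow(data))
    o <- log(data[[pop_col]] / 1e5)
  }
  if (any(y < 0)) abort("outcome must be non-negative.")

  fe_ids <- lapply(fe, function(f) as.integer(factor(data[[f]])))
  names(fe_ids) <- fe

  # drop perfectly separated fixed-effect groups (all-zero outcome)
  keep <- rep(TRUE, length(y))
  dropped_log <- character()
  repeat {
    changed <- FALSE
    for (f in fe) {
      g <- fe_ids[[f]][keep]
      tot <- rowsum(y[keep], g)
      bad <- as.integer(rownames(tot))[tot[, 1] == 0]
      if (length(bad) > 0) {
        hit <- keep & fe_ids[[f]] %in% bad
        dropped_log <- c(dropped_log, sprintf(
          "%s level(s) %s: all-zero outcome (%d obs dropped)",
          f, paste(sort(unique(data[[f]][hit])), collapse = ","), sum(hit)
        ))
        keep[hit] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  if (sum(keep) == 0) abort("all observations dropped by separation check.")
  if (any(!keep)) {
    data <- data[keep, , drop = FALSE]
    X <- X[keep, , drop = FALSE]
    y <- y[keep]
    w <- w[keep]
    o <- o[keep]
    fe_ids <- lapply(fe, function(f) as.integer(factor(data[[f]])))
    names(fe_ids) <- fe
  }

  n <- length(y)
  p <- ncol(X)

  demean <- function(M, weights) {
    # alternating weighted within-group demeaning across all FE sets;
    # fe ids are 1..k integers so rowsum(reorder = TRUE) rows align with ids
    M <- as.matrix(M)
    repeat {
      delta <- 0
      for (ids in fe_ids) {
        num <- rowsum(M * weights, ids, reorder = TRUE)
        den <- as.numeric(rowsum(weights, ids, reorder = TRUE))
        means <- (num / den)[ids, , drop = FALSE]
        M <- M - means
        delta <- max(delta, max(abs(means)))
      }
      if (delta < demean_tol) break
    }
    M
  }

  mu <- (y + stats::weighted.mean(y, w)) / 2
  mu <- pmax(mu, 1e-8)
  xi <- log(mu) - o
  dev_old <- Inf
  converged <- FALSE
  trace <- numeric()
  beta <- NULL
  Xt <- NULL
  zt <- NULL
  W <- NULL
  for (iter in seq_len(max_iter)) {
    W <- w * mu
    z <- xi + (y - mu) / mu
    ZX <- demean(cbind(z, X), W)
    zt <- ZX[, 1]
    Xt <- ZX[, -1, drop = FALSE]
    XtWX <- crossprod(Xt, W * Xt)
    qrA <- qr(XtWX)
    if (qrA$rank < p) {
      bad <- colnames(X)[setdiff(seq_len(p), qrA$pivot[seq_len(qrA$rank)])]
      abort(sprintf(
        "collinear regressor column(s) after fixed-effect absorption: %s",
        paste(bad, collapse = ", ")
      ))
    }
    beta <- solve(qrA, crossprod(Xt, W * zt))
    xi <- (z - zt) + drop(Xt %*% beta)
    mu <- exp(o + xi)
    dev <- 2 * sum(w * (ifelse(y > 0, y * log(y / mu), 0) - (y - mu)))
    trace <- c(trace, dev)
    if (is.finite(dev_old) &&
      abs(dev - dev_old) / (abs(dev_old) + 0.1) < dev_tol) {
      converged <- TRUE
      break
    }
    dev_old <- dev
  }
  if (!converged) {
    abort(sprintf(
      "PPML did not converge in %d iterations; deviance trace: %s",
      max_iter, paste(signif(utils::tail(trace, 5), 8), collapse = ", ")
    ))
  }
  beta <- drop(beta)
  names(beta) <- colnames(X)

  # sandwich covariance on the demeaned system
  k_absorbed <- sum(vapply(fe_ids, function(g) length(unique(g)), 1L)) -
    (length(fe_ids) - 1L)
  k_total <- p + k_absorbed
  A_inv <- solve(crossprod(Xt, W * Xt))
  score <- w * (y - mu)
  if (is.null(cluster)) {
    B <- crossprod(Xt, score^2 * Xt)
    ssc <- n / (n - k_total)
  } else {
    cl <- as.integer(factor(data[[cluster]]))
    S <- rowsum(score * Xt, cl)
    B <- crossprod(S)
    G <- nrow(S)
    ssc <- G / (G - 1) * (n - 1) / (n - k_total)
  }
  V <- ssc * A_inv %*% B %*% A_inv
  V <- (V + t(V)) / 2
  dimnames(V) <- list(names(beta), names(beta))

  # pseudo-likelihood on the count-equivalent scale so that BIC comparisons
  # are invariant to the rate-vs-count parameterisation (in rate mode the
  # population-weighted objective is scaled by the rate denominator)
  d_count <- if (outcome == "rate") w * y / 1e5 else y
  m_count <- if (outcome == "rate") w * mu / 1e5 else mu
  logpl <- sum(d_count * log(m_count) - m_count - lgamma(d_count + 1))
  bic <- -2 * logpl + p * log(n)

  # recover additive fixed-effect decomposition of the absorbed part
  absorbed <- xi - drop(X %*% beta)
  fe_effects <- recover_fe(absorbed, fe_ids, W)
  names(fe_effects) <- fe
  for (f in fe) {
    names(fe_effects[[f]]) <- levels(factor(data[[f]]))
  }

  structure(
    list(
      coefficients = beta, vcov = V, se = sqrt(pmax(diag(V), 0)),
      deviance = trace[length(trace)], logpl = logpl, bic = bic,
      nobs = n, k_explicit = p, k_absorbed = k_absorbed,
      niter = length(trace), converged = converged, trace = trace,
      exposure = exposure, exposure_cols = exposure_cols,
      covariates = covariates, fe = fe, outcome = outcome,
      rate_col = rate_col, deaths_col = deaths_col, pop_col = pop_col,
      cluster = cluster, bases = bases, exposure_spline = exposure_spline,
      data = data, fitted_mu = mu, eta = o + xi, offset = o, weights = w,
      absorbed = absorbed, fe_effects = fe_effects,
      dropped = dropped_log, n_na_dropped = n_na
    ),
    class = "tempmort_ppml"
  )
}

# decompose an absorbed linear-predictor component into additive group
# effects by weighted backfitting; exact at convergence since the component
# lies in the span of the fixed-effect sets
recover_fe <- function(d, fe_ids, w, tol = 1e-10, max_iter = 10000L) {
  effects <- lapply(fe_ids, function(g) numeric(length(unique(g))))
  fit <- rep(0, length(d))
  for (i in seq_len(max_iter)) {
    delta <- 0
    for (j in seq_along(fe_ids)) {
      g <- fe_ids[[j]]
      partial <- d - (fit - effects[[j]][g])
      new_eff <- as.numeric(rowsum(partial * w, g) / rowsum(w, g))
      delta <- max(delta, max(abs(new_eff - effects[[j]])))
      fit <- fit - effects[[j]][g] + new_eff[g]
      effects[[j]] <- new_eff
    }
    if (delta < tol) break
  }
  effects
}

#' Percent change in the monthly mortality rate per additional extreme day
#'
#' Transforms a PPML coefficient to the percentage scale:
#' \eqn{100 (e^{\beta} - 1)}, with the 95% interval
#' \eqn{100 (e^{\beta \pm 1.96\,SE} - 1)} from the robust standard error.
#'
#' @param fit a [ppml_fit()] object.
#' @param term coefficient name(s); defaults to the fit's exposure columns.
#' @param conf_level confidence level.
#' @return A tibble `term`, `pct_change`, `ci_lo`, `ci_hi`, `p_value`.
#' @export
percent_change_per_day <- function(fit, term = NULL, conf_level = 0.95) {
  stopifnot(inherits(fit, "tempmort_ppml"))
  term <- term %||% fit$exposure_cols
  bad <- setdiff(term, names(fit$coefficients))
  if (length(bad) > 0) {
    abort(sprintf("term(s) not in fit: %s", paste(bad, collapse = ", ")))
  }
  b <- fit$coefficients[term]
  se <- fit$se[term]
  ci <- normal_ci(b, se, conf_level)
  tibble::tibble(
    term = term,
    pct_change = unname(100 * expm1(b)),
    ci_lo = unname(100 * expm1(ci$lo)),
    ci_hi = unname(100 * expm1(ci$hi)),
    p_value = unname(2 * pnorm(-abs(b / se)))
  )
}

#' Rank model specifications by the Bayesian information criterion
#'
#' BIC is \eqn{-2 \log PL + k \ln n} with k counting explicit (non-absorbed)
#' parameters. All fits must use identical observations. Ties go to the
#' specification with fewer parameters, then to input order.
#'
#' @param fits a named list of [ppml_fit()] objects.
#' @return A tibble ranked best-first: `spec`, `k`, `n`, `logpl`, `bic`,
#'   `delta_bic`, `rank`.
#' @export
bic_compare <- function(fits) {
  stopifnot(length(fits) >= 1, all(vapply(fits, inherits, TRUE, "tempmort_ppml")))
  if (is.null(names(fits))) names(fits) <- paste0("spec", seq_along(fits))
  ns <- vapply(fits, function(f) f$nobs, 1L)
  if (length(unique(ns)) > 1) {
    abort("fits were not estimated on identical observations (differing n).")
  }
  tab <- tibble::tibble(
    spec = names(fits),
    k = vapply(fits, function(f) f$k_explicit, 1L),
    n = ns,
    logpl = vapply(fits, function(f) f$logpl, 1.0),
    bic = vapply(fits, function(f) f$bic, 1.0),
    input_order = seq_along(fits)
  ) %>%
    dplyr::arrange(.data$bic, .data$k, .data$input_order) %>%
    dplyr::mutate(
      delta_bic = .data$bic - .data$bic[1],
      rank = dplyr::row_number()
    ) %>%
    dplyr::select(-"input_order")
  tab
}
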