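#' Rook-contiguity neighbors on a rectangular county grid
#'
#' @param rows,cols grid dimensions (both >= 1). Counties are numbered
#'   row-major, matching [simulate_study()].
#' @return A tibble `county_id`, `neighbors` (list column of adjacent
#'   county ids), `isolated` (logical; no neighbors).
#' @export
#' @examples
#' build_grid_neighbors(2, 2)
build_grid_neighbors <- function(rows, cols) {
  stopifnot(rows >= 1, cols >= 1)
  idx <- function(r, c) (r - 1L) * cols + c
  nb <- vector("list", rows * cols)
  for (r in seq_len(rows)) {
    for (c in seq_len(cols)) {
      cand <- list(
        if (r > 1) idx(r - 1L, c),
        if (r < rows) idx(r + 1L, c),
        if (c > 1) idx(r, c - 1L),
        if (c < cols) idx(r, c + 1L)
      )
      nb[[idx(r, c)]] <- as.integer(sort(unlist(cand)))
    }
  }
  tibble::tibble(
    county_id = seq_len(rows * cols),
    neighbors = nb,
    isolated = lengths(nb) == 0
  )
}

#' Read / write a neighbor graph as a two-column edge list
#'
#' Each undirected edge is stored once as a `county_id, neighbor_id` pair;
#' reading symmetrises.
#'
#' @param neighbors a neighbor tibble as from [build_grid_neighbors()].
#' @param path CSV file path.
#' @return `read_neighbors()` returns a neighbor tibble covering the ids
#'   present in the file.
#' @export
write_neighbors <- function(neighbors, path) {
  edges <- neighbors %>%
    dplyr::select("county_id", "neighbors") %>%
    tidyr::unnest_longer("neighbors", values_to = "neighbor_id") %>%
    dplyr::filter(.data$county_id < .data$neighbor_id)
  readr::write_csv(edges, path)
  invisible(path)
}

#' @rdname write_neighbors
#' @export
read_neighbors <- function(path) {
  edges <- readr::read_csv(path, show_col_types = FALSE)
  both <- dplyr::bind_rows(
    edges,
    dplyr::rename(edges,
      county_id = "neighbor_id", neighbor_id = "county_id"
    )
  )
  ids <- sort(unique(c(both$county_id, both$neighbor_id)))
  nb <- split(both$neighbor_id, factor(both$county_id, levels = ids))
  tibble::tibble(
    county_id = ids,
    neighbors = unname(purrr::map(nb, ~ as.integer(sort(unique(.x))))),
    isolated = lengths(nb) == 0
  )
}

#' Spatial empirical Bayes smoothing of small-area rates
#'
#' Marshall's (1991) local empirical Bayes estimator: each county's crude
#' rate is shrunk toward the rate of its own neighborhood (the county plus
#' its adjacent counties) by a factor reflecting how much of the local rate
#' variance is signal rather than Poisson noise. With neighborhood
#' \eqn{J(i) = N(i) \cup \{i\}}:
#' \deqn{m_i = \sum_J y_j / \sum_J n_j, \quad
#'   s^2_i = \sum_J n_j (r_j - m_i)^2 / \sum_J n_j}
#' \deqn{w_i = \frac{(s^2_i - m_i/\bar n_i)_+}
#'   {(s^2_i - m_i/\bar n_i)_+ + m_i/n_i}, \quad
#'   \hat r_i = m_i + w_i (r_i - m_i)}
#' where \eqn{\bar n_i} is the mean neighborhood population. A negative
#' prior-variance estimate is truncated to zero, i.e. full shrinkage to the
#' local mean. Counties without neighbors fall back to the same estimator
#' computed on the pooled set of all counties (global empirical Bayes).
#'
#' @param counts non-negative event counts per county.
#' @param populations positive person denominators, aligned with `counts`.
#' @param neighbors neighbor tibble ([build_grid_neighbors()] /
#'   [read_neighbors()]) whose `county_id` aligns with the order of
#'   `counts`; alternatively a plain list of neighbor index vectors.
#' @return A tibble `county_id`, `raw_rate`, `local_mean`,
#'   `shrinkage_weight`, `smoothed_rate` (rates on the per-person scale).
#' @export
eb_local_smooth <- function(counts, populations, neighbors) {
  if (any(counts < 0)) abort("counts must be non-negative.")
  if (any(populations <= 0)) abort("populations must be positive.")
  if (tibble::is_tibble(neighbors) || is.data.frame(neighbors)) {
    nb <- neighbors$neighbors
    ids <- neighbors$county_id
  } else {
    nb <- neighbors
    ids <- seq_along(nb)
  }
  n <- length(counts)
  stopifnot(length(populations) == n, length(nb) == n)
  rates <- counts / populations
  out <- purrr::map(seq_len(n), function(i) {
    j <- c(i, match(nb[[i]], ids))
    if (length(nb[[i]]) == 0) j <- seq_len(n) # isolated: global EB
    pop_j <- populations[j]
    if (sum(pop_j) <= 0) abort("zero total neighborhood population.")
    m <- sum(counts[j]) / sum(pop_j)
    s2 <- sum(pop_j * (rates[j] - m)^2) / sum(pop_j)
    pbar <- mean(pop_j)
    a <- max(s2 - m / pbar, 0)
    w <- if (a == 0 && m == 0) 0 else a / (a + m / populations[i])
    tibble::tibble(
      local_mean = m,
      shrinkage_weight = w,
      smoothed_rate = m + w * (rates[i] - m)
    )
  }) %>% dplyr::bind_rows()
  tibble::tibble(
    county_id = ids,
    raw_rate = rates
  ) %>% dplyr::bind_cols(out)
}

#' Smooth a county-month mortality panel before model fitting
#'
#' Computes one shrinkage per county on period-aggregate deaths and
#' person-months (pooling across the study period for stability), then
#' rescales each county's monthly rates by the ratio of smoothed to raw
#' period rate. Smoothing by age group keeps strata independent. With
#' `enabled = FALSE` the panel is returned untouched, supporting
#' sensitivity toggling.
#'
#' @param mortality a mortality panel (`county_id`, `year`, `month`,
#'   `age_group`, `deaths`, `population`, `rate` per 100k).
#' @param neighbors a neighbor tibble covering all counties.
#' @param enabled set `FALSE` to bypass smoothing.
#' @param monthly if `TRUE`, smooth each calendar month's pooled rates
#'   separately instead of the whole-period aggregate.
#' @return The panel with `rate` replaced by its smoothed value and the
#'   original kept as `rate_raw`.
#' @export
smooth_mortality <- function(mortality, neighbors, enabled = TRUE,
                             monthly = FALSE) {
  check_columns(
    mortality,
    c("county_id", "year", "month", "age_group", "deaths", "population"),
    "mortality"
  )
  if (!enabled) {
    return(dplyr::mutate(mortality, rate_raw = .data$rate))
  }
  grouping <- if (monthly) c("age_group", "month") else "age_group"
  factors <- mortality %>%
    dplyr::group_by(dplyr::across(dplyr::all_of(c(grouping, "county_id")))) %>%
    dplyr::summarise(
      deaths = sum(.data$deaths),
      person_months = sum(.data$population),
      .groups = "drop"
    ) %>%
    dplyr::group_by(dplyr::across(dplyr::all_of(grouping))) %>%
    dplyr::group_modify(function(d, key) {
      d <- d[match(neighbors$county_id, d$county_id), ]
      sm <- eb_local_smooth(d$deaths, d$person_months, neighbors)
      tibble::tibble(
        county_id = d$county_id,
        smooth_factor = ifelse(sm$raw_rate > 0,
          sm$smoothed_rate / sm$raw_rate, 1
        )
      )
    }) %>%
    dplyr::ungroup()
  mortality %>%
    dplyr::left_join(factors, by = c(grouping, "county_id")) %>%
    dplyr::mutate(
      rate_raw = .data$rate,
      rate = .data$rate * .data$smooth_factor
    ) %>%
    dplyr::select(-"smooth_factor")
}
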