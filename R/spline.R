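#' Restricted (natural) cubic spline basis
#'
#' Builds the standard restricted cubic spline design: cubic between knots,
#' linear beyond the terminal knots, continuous with continuous first and
#' second derivatives everywhere. With k knots the basis has k - 1 columns,
#' the first being the untransformed linear term; the remaining columns are
#' the scaled truncated-power combinations
#' \deqn{\frac{(x-t_j)_+^3 - (x-t_{k-1})_+^3 \frac{t_k-t_j}{t_k-t_{k-1}}
#'   + (x-t_k)_+^3 \frac{t_{k-1}-t_j}{t_k-t_{k-1}}}{(t_k-t_1)^2}}
#' for \eqn{j = 1, \dots, k-2}.
#'
#' Default knots sit at conventional sample-percentile positions
#' (e.g. 5/35/65/95 for 4 knots).
#'
#' @param x numeric vector.
#' @param n_knots number of knots (>= 3); ignored when `knots` supplied.
#' @param knots optional explicit knot locations (sorted).
#' @return A numeric matrix with `length(knots) - 1` columns and attributes
#'   `knots` (locations) and class `tempmort_rcs`. Use
#'   [predict_rcs()] to evaluate the same basis at new points.
#' @export
#' @examples
#' b <- rcs_basis(runif(200), n_knots = 4)
#' ncol(b) # 3
rcs_basis <- function(x, n_knots = 4, knots = NULL) {
  if (is.null(knots)) {
    if (n_knots < 3) abort("n_knots must be >= 3.")
    probs <- switch(as.character(n_knots),
      "3" = c(10, 50, 90),
      "4" = c(5, 35, 65, 95),
      "5" = c(5, 27.5, 50, 72.5, 95),
      "6" = c(5, 23, 41, 59, 77, 95),
      "7" = c(2.5, 18.33, 34.17, 50, 65.83, 81.67, 97.5),
      seq(2.5, 97.5, length.out = n_knots)
    ) / 100
    knots <- quantile(x, probs, type = 7, names = FALSE)
    if (length(unique(x)) < length(knots)) {
      abort("x has too few distinct values for the requested knots.")
    }
  }
  knots <- sort(knots)
  if (length(unique(knots)) < length(knots)) {
    abort("knot locations must be distinct (x may have too few distinct values).")
  }
  k <- length(knots)
  out <- matrix(0, length(x), k - 1)
  out[, 1] <- x
  tk <- knots[k]
  tk1 <- knots[k - 1]
  scale2 <- (tk - knots[1])^2
  cube <- function(u) pmax(u, 0)^3
  for (j in seq_len(k - 2)) {
    out[, j + 1] <- (cube(x - knots[j]) -
      cube(x - tk1) * (tk - knots[j]) / (tk - tk1) +
      cube(x - tk) * (tk1 - knots[j]) / (tk - tk1)) / scale2
  }
  colnames(out) <- c("lin", paste0("ns", seq_len(k - 2)))
  structure(out, knots = knots, class = c("tempmort_rcs", "matrix", "array"))
}

#' Evaluate a fitted restricted cubic spline basis at new points
#'
#' @param basis a basis returned by [rcs_basis()].
#' @param newx numeric vector of evaluation points.
#' @return Matrix of basis values at `newx` with the training knots.
#' @export
predict_rcs <- function(basis, newx) {
  rcs_basis(newx, knots = attr(basis, "knots"))
}
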