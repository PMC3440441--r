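#' Spline basis for optimal-scaling transformations
#'
#' Builds the piecewise-polynomial basis used for spline analysis levels.
#' Interior knots are placed at quantiles of the category distribution
#' (weighted by category frequency). The monotone variant returns a
#' cumulated B-spline basis whose nonnegative combinations (plus a free
#' intercept) are nondecreasing.
#'
#' @param positions numeric category positions (original category codes),
#'   strictly increasing.
#' @param degree spline degree (default 2, quadratic).
#' @param interior_knots number of interior knots (0, 1 or 2 typical).
#' @param monotone logical; if `TRUE` return the integrated basis for
#'   monotone (spline-ordinal) fits.
#' @param weights category frequencies used for knot placement; default
#'   equal.
#' @return list with `basis` (length(positions) x df matrix, first column is
#'   the intercept), `knots` (interior knots used), `degree`,
#'   `interior_knots` (possibly reduced), `monotone`.
#' @details If there are too few distinct positions to support the requested
#'   knot count (fewer than `degree + interior_knots + 1`), the knot count is
#'   reduced and a warning is emitted.
#' @export
spline_basis <- function(positions, degree = 2L, interior_knots = 1L,
                         monotone = FALSE, weights = NULL) {
  stopifnot(degree >= 1L, interior_knots >= 0L)
  k <- length(positions)
  if (is.unsorted(positions, strictly = TRUE))
    stop("category positions must be strictly increasing")
  if (is.null(weights)) weights <- rep(1, k)
  # need df = degree + knots + 1 <= k for an identifiable basis
  nk <- as.integer(interior_knots)
  while (nk > 0L && degree + nk + 1L > k) {
    nk <- nk - 1L
  }
  if (nk < interior_knots)
    warning(sprintf("reduced interior knots from %d to %d (only %d categories)",
                    interior_knots, nk, k))
  rng <- range(positions)
  knots <- numeric(0)
  if (nk > 0L) {
    probs <- seq_len(nk) / (nk + 1L)
    knots <- stats::quantile(rep.int(positions, pmax(1L, round(weights))),
                             probs = probs, names = FALSE, type = 7)
    # knots must be strictly interior and distinct; else fall back to
    # equally spaced interior knots
    if (any(knots <= rng[1]) || any(knots >= rng[2]) || anyDuplicated(knots)) {
      knots <- rng[1] + diff(rng) * seq_len(nk) / (nk + 1L)
    }
  }
  B <- splines::bs(positions, knots = knots, degree = degree,
                   intercept = TRUE, Boundary.knots = rng)
  B <- unclass(B)[, , drop = FALSE]
  if (monotone) {
    # right-to-left cumulative sums of a B-spline partition of unity give a
    # nondecreasing basis; column 1 becomes the constant 1 (intercept)
    B <- t(apply(B, 1L, function(row) rev(cumsum(rev(row)))))
    if (k == 1L) B <- matrix(B, nrow = 1L)
  }
  list(basis = B, knots = knots, degree = degree, interior_knots = nk,
       monotone = monotone)
}

# Weighted least-squares projection of target values m (per category, with
# frequency weights d) onto the span of a spline basis. Returns the fitted
# values. For the monotone basis, coefficients on the non-intercept columns
# are constrained nonnegative (intercept free), giving a nondecreasing fit.
spline_project <- function(m, d, sb) {
  B <- sb$basis
  sw <- sqrt(d)
  if (!sb$monotone) {
    fit <- stats::lm.wfit(x = B, y = m, w = d)
    return(drop(B %*% ifelse(is.na(fit$coefficients), 0, fit$coefficients)))
  }
  # absorb the free intercept: center out the weighted mean, fit remaining
  # columns with nonnegative coefficients
  mu_m <- sum(d * m) / sum(d)
  Bm <- B[, -1L, drop = FALSE]
  mu_B <- colSums(d * Bm) / sum(d)
  Bc <- sweep(Bm, 2L, mu_B)
  cf <- nnls_fit(sw * Bc, sw * (m - mu_m))
  mu_m + drop(Bc %*% cf)
}
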