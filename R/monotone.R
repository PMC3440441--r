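#' Weighted monotone (isotonic) regression
#'
#' Pool-adjacent-violators algorithm for the weighted least-squares monotone
#' nondecreasing fit. Used to project unconstrained category quantifications
#' onto the ordinal feasible set, with category frequencies as weights.
#'
#' @param values numeric vector of target values.
#' @param weights positive case weights, same length as `values`.
#' @return numeric vector of the same length: the nondecreasing fit; pooled
#'   blocks carry the weighted mean of their members.
#' @examples
#' monotone_regression(c(1, 3, 2))          # c(1, 2.5, 2.5)
#' monotone_regression(c(2, 1), c(3, 1))    # c(1.75, 1.75)
#' @export
monotone_regression <- function(values, weights = rep(1, length(values))) {
  n <- length(values)
  stopifnot(length(weights) == n, all(is.finite(values)), all(weights > 0))
  if (n <= 1L) return(values)
  # stack of blocks: value (weighted mean), weight, size
  bv <- numeric(n); bw <- numeric(n); bs <- integer(n)
  top <- 0L
  for (i in seq_len(n)) {
    top <- top + 1L
    bv[top] <- values[i]; bw[top] <- weights[i]; bs[top] <- 1L
    while (top > 1L && bv[top - 1L] > bv[top]) {
      w <- bw[top - 1L] + bw[top]
      bv[top - 1L] <- (bw[top - 1L] * bv[top - 1L] + bw[top] * bv[top]) / w
      bw[top - 1L] <- w
      bs[top - 1L] <- bs[top - 1L] + bs[top]
      top <- top - 1L
    }
  }
  rep.int(bv[seq_len(top)], bs[seq_len(top)])
}

# Lawson-Hanson active-set nonnegative least squares: minimize ||A x - b||^2
# subject to x >= 0. Problems here are tiny (<= ~6 columns), so a plain R
# implementation is adequate.
nnls_fit <- function(A, b, tol = 1e-10) {
  p <- ncol(A)
  x <- numeric(p)
  passive <- rep(FALSE, p)
  w <- drop(crossprod(A, b))           # gradient at x = 0
  it <- 0L
  while (any(!passive & w > tol) && it < 30L * p) {
    it <- it + 1L
    j <- which.max(ifelse(passive, -Inf, w))
    passive[j] <- TRUE
    repeat {
      s <- numeric(p)
      Ap <- A[, passive, drop = FALSE]
      sp <- tryCatch(qr.coef(qr(Ap), b), error = function(e) NULL)
      if (is.null(sp)) { passive[j] <- FALSE; break }
      sp[is.na(sp)] <- 0
      s[passive] <- sp
      if (all(s[passive] > tol)) { x <- s; break }
      bad <- passive & s <= tol
      alpha <- min(x[bad] / (x[bad] - s[bad]))
      x <- x + alpha * (s - x)
      passive <- passive & x > tol
      x[!passive] <- 0
      if (!any(passive)) { x[] <- 0; break }
    }
    r <- b - drop(A %*% x)
    w <- drop(crossprod(A, r))
  }
  x
}
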