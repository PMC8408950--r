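#' Poisson upper-tail probability
#'
#' `P(X >= k)` for `X ~ Poisson(lambda)`, i.e. `1 - CDF(k - 1)`, evaluated via
#' the regularized-gamma route of `ppois(..., lower.tail = FALSE)` so it stays
#' accurate deep in the tail where the naive `1 - ppois(k - 1, lambda)` would
#' round to 0 or lose digits. The tail is inclusive: observing exactly the
#' expectation is not evidence of excess.
#'
#' @param k Non-negative integer observation(s).
#' @param lambda Positive expectation.
#' @return Probabilities in `[0, 1]`, vectorised over `k`.
#' @export
poisson_upper_tail <- function(k, lambda) {
  stop_if(any(lambda <= 0), "lambda must be > 0")
  stop_if(any(k < 0), "k must be >= 0")
  ifelse(k == 0, 1, stats::ppois(k - 1, lambda, lower.tail = FALSE))
}

#' Benjamini-Hochberg adjusted values
#'
#' Step-up FDR adjustment: with order statistics `p_(1) <= ... <= p_(m)`,
#' `q_(i) = min_{j >= i} m * p_(j) / j`, capped at 1, returned in the input
#' order. Ties share identical adjusted values.
#'
#' @param pvals Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted values (q-values), same length and order as `pvals`.
#' @export
bh_adjust <- function(pvals) {
  stop_if(any(pvals < 0 | pvals > 1, na.rm = TRUE), "p-values must be in [0, 1]")
  m <- length(pvals)
  if (m == 0L) return(numeric(0))
  o <- order(pvals)                     # stable for ties
  q <- pvals[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}
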