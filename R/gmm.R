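#' Fit a one-dimensional Gaussian mixture by EM with BIC model selection
#'
#' Small expectation-maximization fitter for univariate Gaussian mixtures.
#' Both an equal-variance and an unequal-variance family are fitted for every
#' component count in `G_range` and the model is chosen by BIC (free
#' parameters: `2G` for equal variance, `3G - 1` for unequal).
#' Initialisation is deterministic: component means start at evenly spaced
#' quantiles, so a fixed input gives a fixed fit. Variances are floored to
#' avoid collapse on near-duplicate points.
#'
#' @param x Numeric data vector.
#' @param G_range Candidate component counts (default 1:3).
#' @param max_iter,tol EM iteration cap and log-likelihood tolerance.
#' @param var_floor Minimum component variance, relative to `var(x)`.
#' @return List of class `gmm1d`: `G`, `model` (`"E"` equal / `"V"` varying
#'   variance), `mean`, `sd`, `weight`, `classification` (hard assignment by
#'   maximum posterior), `bic`, `loglik`, `bic_all`.
#' @export
fit_gmm1d <- function(x, G_range = 1:3, max_iter = 500L, tol = 1e-8,
                      var_floor = 1e-6) {
  n <- length(x)
  stop_if(n < 2L, "need at least 2 observations")
  G_range <- G_range[G_range <= length(unique(x))]
  if (length(G_range) == 0L) G_range <- 1L
  vx <- stats::var(x)
  if (!is.finite(vx) || vx <= 0) vx <- 1e-12
  floor_v <- var_floor * vx

  fit_one <- function(G, model) {
    if (G == 1L) {
      mu <- mean(x); v <- max(vx * (n - 1) / n, floor_v)
      ll <- sum(stats::dnorm(x, mu, sqrt(v), log = TRUE))
      return(list(G = 1L, model = model, mean = mu, sd = sqrt(v), weight = 1,
                  loglik = ll, resp = matrix(1, n, 1)))
    }
    mu <- stats::quantile(x, probs = (seq_len(G) - 0.5) / G, names = FALSE)
    v <- rep(max(vx / G, floor_v), G)
    w <- rep(1 / G, G)
    ll_old <- -Inf
    resp <- matrix(0, n, G)
    for (iter in seq_len(max_iter)) {
      dens <- vapply(seq_len(G),
                     function(g) w[g] * stats::dnorm(x, mu[g], sqrt(v[g])),
                     numeric(n))
      tot <- rowSums(dens)
      tot[tot <= 0 | !is.finite(tot)] <- .Machine$double.xmin
      resp <- dens / tot
      nk <- colSums(resp)
      nk[nk < 1e-10] <- 1e-10
      w <- nk / n
      mu <- colSums(resp * x) / nk
      ss <- colSums(resp * (outer(x, mu, "-"))^2)
      v <- if (model == "E") rep(max(sum(ss) / n, floor_v), G)
           else pmax(ss / nk, floor_v)
      ll <- sum(log(tot))
      if (is.finite(ll) && abs(ll - ll_old) < tol * (abs(ll) + 1)) break
      ll_old <- ll
    }
    list(G = G, model = model, mean = mu, sd = sqrt(v), weight = w,
         loglik = ll, resp = resp)
  }

  grid <- expand.grid(G = G_range, model = c("E", "V"),
                      stringsAsFactors = FALSE)
  grid <- grid[!(grid$G == 1L & grid$model == "V"), , drop = FALSE]
  fits <- Map(fit_one, grid$G, grid$model)
  bics <- vapply(fits, function(f) {
    npar <- if (f$model == "E") 2L * f$G else 3L * f$G - 1L
    if (f$G == 1L) npar <- 2L
    -2 * f$loglik + npar * log(n)
  }, numeric(1))
  best <- fits[[which.min(bics)]]
  cls <- max.col(best$resp, ties.method = "first")
  structure(list(G = best$G, model = best$model, mean = best$mean,
                 sd = best$sd, weight = best$weight, classification = cls,
                 bic = min(bics), loglik = best$loglik,
                 bic_all = stats::setNames(
                   bics, paste0(grid$model, grid$G))),
            class = "gmm1d")
}
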