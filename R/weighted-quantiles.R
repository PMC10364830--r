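#' Weighted quantiles and quantile ranks
#'
#' `weighted_quantile()` inverts the sample-weighted empirical distribution
#' function with linear interpolation between distinct order statistics placed
#' at normalized cumulative-weight midpoints: the i-th distinct value sits at
#' plotting position \eqn{(c_i - w_i/2)/W}, where \eqn{c_i} is the cumulative
#' weight through that value, \eqn{w_i} the (tie-pooled) weight on it, and
#' \eqn{W} the total weight. With unit weights this is the Hazen convention
#' (R's `quantile()` type 5). `weighted_rank()` is its inverse: the
#' interpolated weighted-ECDF position of a value, so that
#' `weighted_rank(x, weighted_quantile(x, p, w), w) == p` throughout the
#' interpolation range.
#'
#' Ties pool their weights and share the midpoint position of the pooled
#' block, which keeps both functions deterministic and symmetric under
#' reordering. Probabilities below the first midpoint return the minimum and
#' above the last return the maximum (`p = 0` and `p = 1` are exactly the
#' sample extremes); values below the minimum rank 0, above the maximum 1.
#'
#' @param x Numeric vector of observations (BMI values here, but any sample).
#' @param probs Probabilities in \[0, 1\] at which to evaluate the quantile.
#' @param v Numeric vector of values whose weighted-ECDF position is wanted.
#' @param w Positive sampling weights, recycled `NULL` to unit weights.
#' @return `weighted_quantile()`: numeric vector, one quantile per element of
#'   `probs`. `weighted_rank()`: numeric vector of probabilities in \[0, 1\].
#' @export
#' @examples
#' weighted_quantile(c(1, 2, 3), 0.5) # unweighted median
#' weighted_quantile(c(10, 20, 30, 40), 0.9, w = c(1, 1, 1, 5))
#' weighted_rank(c(10, 20, 30, 40), 40, w = c(1, 1, 1, 5))
weighted_quantile <- function(x, probs, w = NULL) {
  pts <- ecdf_points(x, w)
  if (length(probs) == 0) {
    return(numeric(0))
  }
  if (any(is.na(probs)) || any(probs < 0) || any(probs > 1)) {
    abort("`probs` must lie in [0, 1] with no missing values.")
  }
  if (length(pts$values) == 1L) {
    return(rep(pts$values, length(probs)))
  }
  approx(pts$pos, pts$values, xout = probs, rule = 2, ties = "ordered")$y
}

#' @rdname weighted_quantile
#' @export
weighted_rank <- function(x, v, w = NULL) {
  pts <- ecdf_points(x, w)
  if (length(v) == 0) {
    return(numeric(0))
  }
  if (any(is.na(v))) {
    abort("`v` must not contain missing values.")
  }
  if (length(pts$values) == 1L) {
    r <- rep(0.5, length(v))
  } else {
    r <- approx(pts$values, pts$pos, xout = v, rule = 2, ties = "ordered")$y
  }
  r[v < pts$values[1L]] <- 0
  r[v > pts$values[length(pts$values)]] <- 1
  r
}

# sorted distinct values with tie-pooled weights and midpoint positions
ecdf_points <- function(x, w = NULL) {
  if (length(x) == 0) {
    abort("Cannot compute weighted quantiles of an empty sample.")
  }
  if (is.null(w)) w <- rep(1, length(x))
  if (length(w) != length(x)) {
    abort("`w` must have the same length as `x`.")
  }
  if (any(is.na(x)) || any(!is.finite(x))) {
    abort("`x` must be finite with no missing values.")
  }
  if (any(is.na(w)) || any(w <= 0)) {
    abort("Sampling weights must be positive with no missing values.")
  }
  o <- order(x)
  xs <- x[o]
  ws <- w[o]
  first <- !duplicated(xs)
  grp <- cumsum(first)
  wu <- as.numeric(rowsum(ws, grp, reorder = FALSE))
  cw <- cumsum(wu)
  list(values = xs[first], pos = (cw - wu / 2) / cw[length(cw)])
}

# right-continuous weighted ECDF evaluated at `at` (used by the KS statistic)
weighted_ecdf_at <- function(x, w, at) {
  o <- order(x)
  xs <- x[o]
  cw <- cumsum(w[o]) / sum(w)
  idx <- findInterval(at, xs)
  c(0, cw)[idx + 1L]
}

#' Weighted two-sample Kolmogorov-Smirnov comparison
#'
#' Compares two weighted samples through their weighted empirical cumulative
#' distribution functions. The statistic is
#' \eqn{D = \sup_t |F_a(t) - F_b(t)|} evaluated over the pooled support, with
#' each observation contributing its sampling weight. The p-value uses the
#' asymptotic Kolmogorov distribution with the effective sample sizes
#' \eqn{n_{eff} = (\sum w)^2 / \sum w^2}, so with unit weights the result
#' coincides with the classical (asymptotic) two-sample test of
#' [stats::ks.test()].
#'
#' @param x,y Numeric samples to compare (e.g. corrected and measured BMI).
#' @param wx,wy Positive sampling weights; `NULL` means unit weights.
#' @return A one-row tibble with `statistic` (D), `p_value`, and the two
#'   effective sample sizes `n_eff_a`, `n_eff_b`.
#' @export
#' @examples
#' ks_compare(rnorm(50), rnorm(50))
ks_compare <- function(x, y, wx = NULL, wy = NULL) {
  if (length(x) == 0 || length(y) == 0) {
    abort("Both samples must be nonempty.")
  }
  if (is.null(wx)) wx <- rep(1, length(x))
  if (is.null(wy)) wy <- rep(1, length(y))
  if (any(c(wx, wy) <= 0) || anyNA(c(wx, wy))) {
    abort("Sampling weights must be positive with no missing values.")
  }
  if (anyNA(x) || anyNA(y)) {
    abort("Samples must not contain missing values.")
  }
  at <- sort(unique(c(x, y)))
  d <- max(abs(weighted_ecdf_at(x, wx, at) - weighted_ecdf_at(y, wy, at)))
  n_eff <- function(w) sum(w)^2 / sum(w^2)
  na <- n_eff(wx)
  nb <- n_eff(wy)
  n <- na * nb / (na + nb)
  tibble::tibble(
    statistic = d,
    p_value = kolmogorov_sf(sqrt(n) * d),
    n_eff_a = na,
    n_eff_b = nb
  )
}

# survival function of the Kolmogorov distribution, P(sup|B(t)| > t); both
# series branches as in the classical asymptotic two-sample test
kolmogorov_sf <- function(t) {
  if (t < 1e-8) {
    return(1)
  }
  if (t < 1) {
    k <- seq_len(40L)
    p <- 1 - sqrt(2 * pi) / t * sum(exp(-(2 * k - 1)^2 * pi^2 / (8 * t^2)))
  } else {
    k <- seq_len(100L)
    p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * t^2))
  }
  min(1, max(0, p))
}
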