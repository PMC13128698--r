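#' Quantiles of an effect-size distribution, optionally weighted
#'
#' Unweighted quantiles use linear interpolation between order statistics
#' (the index `h = p (n - 1)` convention, i.e. `stats::quantile()` type 7).
#' With weights `w` (here typically inverse variances `1 / sei^2`) the sorted
#' values receive midpoint cumulative weights
#' `c_k = (sum_{j<=k} w_j - w_k / 2) / sum(w)` and the estimate interpolates
#' the sorted values at `t = c_1 + p (c_n - c_1)` — the affine placement of
#' `p` on `[c_1, c_n]` under which equal weights reproduce the unweighted
#' estimator exactly.
#'
#' @param x Numeric vector of effect sizes.
#' @param probs Probabilities in `[0, 1]` (vectorised).
#' @param weights Optional positive weights, same length as `x`.
#' @return Numeric vector of quantiles, one per probability.
#' @examples
#' esd_quantile(1:7, 0.25) # 2.5
#' @export
esd_quantile <- function(x, probs, weights = NULL) {
  if (length(x) == 0) abort_validation("`x` must be non-empty.")
  if (any(!is.finite(x))) abort_validation("`x` must be finite.")
  if (any(probs < 0 | probs > 1)) {
    abort_validation("`probs` must lie in [0, 1].")
  }
  if (is.null(weights)) {
    return(stats::quantile(x, probs, type = 7, names = FALSE))
  }
  if (length(weights) != length(x)) {
    abort_validation("`weights` must have the same length as `x`.")
  }
  if (any(!is.finite(weights) | weights <= 0)) {
    abort_validation("`weights` must be positive and finite.")
  }
  n <- length(x)
  if (n == 1) return(rep(x, length(probs)))
  ord <- order(x)
  xs <- x[ord]
  w <- weights[ord]
  cw <- (cumsum(w) - w / 2) / sum(w)
  t <- cw[1] + probs * (cw[n] - cw[1])
  stats::approx(cw, xs, xout = t, ties = "ordered")$y
}

#' Percentile-bootstrap confidence interval for a quantile
#'
#' Resamples the data with replacement `n_boot` times, computes the requested
#' quantile(s) on each replicate, and returns the empirical
#' `(1 - level)/2` and `1 - (1 - level)/2` percentiles of the replicate
#' distribution. With weights, resampling draws observations with probability
#' proportional to their weight (inverse-variance resampling), and the
#' replicate quantile is unweighted — the weights are consumed by the
#' resampling step. Deterministic given `seed`; the global RNG state is left
#' untouched.
#'
#' @param x Numeric vector.
#' @param probs Quantile probabilities (vectorised).
#' @param n_boot Number of bootstrap replicates.
#' @param seed Integer seed (required, for reproducibility).
#' @param level Confidence level, default 0.95.
#' @param weights Optional positive resampling weights.
#' @return A tibble with one row per probability: `prob`, `low`, `high`,
#'   `n_boot`, `level`.
#' @export
bootstrap_quantile_ci <- function(x, probs, n_boot = 2000, seed,
                                  level = 0.95, weights = NULL) {
  if (length(x) == 0) abort_validation("`x` must be non-empty.")
  if (n_boot < 1) abort_validation("`n_boot` must be >= 1.")
  if (missing(seed) || is.null(seed)) {
    abort_validation("an integer `seed` is required for the bootstrap.")
  }
  if (level <= 0 || level >= 1) abort_validation("`level` must be in (0, 1).")
  n <- length(x)
  reps <- withr::with_seed(as.integer(seed), {
    idx <- sample.int(n, n * n_boot, replace = TRUE, prob = weights)
    m <- matrix(x[idx], nrow = n)
    apply(m, 2, stats::quantile, probs = probs, type = 7, names = FALSE)
  })
  reps <- matrix(reps, nrow = length(probs))
  a <- (1 - level) / 2
  tibble::tibble(
    prob = probs,
    low = apply(reps, 1, stats::quantile, probs = a, type = 7, names = FALSE),
    high = apply(reps, 1, stats::quantile, probs = 1 - a, type = 7, names = FALSE),
    n_boot = as.integer(n_boot),
    level = level
  )
}

#' Bowley's quartile skewness coefficient
#'
#' `(Q1 + Q3 - 2 Q2) / (Q3 - Q1)`, a robust skewness measure based on the
#' middle 50% of the distribution, bounded in `[-1, 1]`; 0 indicates no
#' skewness, positive values right skewness (small-study bias in an
#' effect-size distribution typically shows up as right skew).
#'
#' @param x A numeric vector, or a data frame with the effect column `es`.
#' @param weights Optional positive weights passed to [esd_quantile()].
#' @param es Effect column name when `x` is a data frame.
#' @return The skewness coefficient.
#' @export
bowley_skewness <- function(x, weights = NULL, es = "yi") {
  v <- pull_effects(x, es)
  q <- esd_quantile(v, c(0.25, 0.5, 0.75), weights)
  if (q[3] <= q[1]) {
    abort_validation("Bowley skewness undefined: Q3 equals Q1.")
  }
  unname((q[1] + q[3] - 2 * q[2]) / (q[3] - q[1]))
}

#' Split a distribution at a smallest effect size of interest
#'
#' Reports which proportion of the (by default absolute) effect-size
#' distribution falls below a SESOI and which proportion is equal to or
#' greater than it. The two proportions always sum to one.
#'
#' @param x A numeric vector, or a data frame with effect column `es`.
#' @param sesoi Smallest effect size of interest.
#' @param absolute Compare magnitudes rather than signed values (default).
#' @param es Effect column name when `x` is a data frame.
#' @return A one-row tibble: `sesoi`, `prop_below`, `prop_at_or_above`, `n`.
#' @examples
#' sesoi_split(c(0.1, 0.2, 0.3, 0.4), sesoi = 0.3)
#' @export
sesoi_split <- function(x, sesoi, absolute = TRUE, es = "yi") {
  v <- pull_effects(x, es)
  if (absolute) v <- abs(v)
  at_or_above <- mean(v >= sesoi)
  tibble::tibble(
    sesoi = sesoi,
    prop_below = 1 - at_or_above,
    prop_at_or_above = at_or_above,
    n = length(v)
  )
}

#' Percentile rank of an observed effect within a distribution
#'
#' The percentage of effects strictly smaller than the observed value —
#' "our effect was larger than X% of effects reported in the field". With
#' `absolute = TRUE` both the distribution and the observed effect are
#' compared in magnitude.
#'
#' @param x A numeric vector, or a data frame with effect column `es`.
#' @param value Observed effect size.
#' @param absolute Compare magnitudes (default).
#' @param es Effect column name when `x` is a data frame.
#' @return Percentage in `[0, 100]`.
#' @export
percentile_rank <- function(x, value, absolute = TRUE, es = "yi") {
  v <- pull_effects(x, es)
  if (absolute) {
    v <- abs(v)
    value <- abs(value)
  }
  100 * mean(v < value)
}

pull_effects <- function(x, es = "yi") {
  if (is.data.frame(x)) {
    if (!es %in% names(x)) {
      abort_validation(sprintf("column `%s` not found.", es))
    }
    x <- x[[es]]
  }
  if (length(x) == 0) abort_validation("effect-size vector must be non-empty.")
  as.numeric(x)
}
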