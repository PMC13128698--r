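#' Power of a t test via the noncentral t distribution
#'
#' For a paired or one-sample design the test statistic has `n - 1` degrees
#' of freedom and noncentrality `d sqrt(n)`; for a two-sample design with
#' `n` per group, `2n - 2` degrees of freedom and noncentrality
#' `d sqrt(n / 2)`. Power is the probability mass of the noncentral t beyond
#' the central-t critical value; the two-tailed variant includes the (tiny)
#' lower rejection region.
#'
#' @param d Hypothesised standardised effect size (Cohen's d / Hedges' g).
#' @param n Sample size: number of pairs (paired/one-sample) or per group
#'   (two-sample), `>= 2`.
#' @param alpha Type-I error rate, in (0, 1); default 0.05.
#' @param tails `"one"` or `"two"`.
#' @param design `"paired"` (also one-sample) or `"two_sample"` (equal n).
#' @return Power, a probability. At `d = 0` one-tailed power equals `alpha`.
#' @examples
#' power_t(d = 0.4, n = 27, tails = "one", design = "paired")
#' @export
power_t <- function(d, n, alpha = 0.05, tails = c("one", "two"),
                    design = c("paired", "two_sample")) {
  tails <- match.arg(tails)
  design <- match.arg(design)
  check_power_args(n, alpha)
  if (!is.finite(d)) abort_validation("`d` must be finite.")
  df <- switch(design, paired = n - 1, two_sample = 2 * n - 2)
  ncp <- switch(design, paired = d * sqrt(n), two_sample = d * sqrt(n / 2))
  if (tails == "one") {
    tc <- stats::qt(1 - alpha, df)
    stats::pt(tc, df, ncp = ncp, lower.tail = FALSE)
  } else {
    tc <- stats::qt(1 - alpha / 2, df)
    stats::pt(tc, df, ncp = ncp, lower.tail = FALSE) +
      stats::pt(-tc, df, ncp = ncp)
  }
}

check_power_args <- function(n, alpha) {
  if (any(n < 2) || any(n != floor(n))) {
    abort_validation("`n` must be an integer >= 2.")
  }
  if (alpha <= 0 || alpha >= 1) abort_validation("`alpha` must be in (0, 1).")
}

#' Smallest sample size reaching a target power
#'
#' Searches the integers (doubling to bracket, then bisection) for the
#' smallest `n >= 2` whose power reaches the target. The effect size enters
#' by magnitude.
#'
#' @param d Standardised effect size, nonzero.
#' @param power Target power in (0, 1), default 0.80.
#' @inheritParams power_t
#' @return Smallest integer sample size with `power_t(...) >= power`.
#' @examples
#' required_n(d = 0.5, power = 0.80, tails = "one", design = "paired") # 27
#' @export
required_n <- function(d, power = 0.80, alpha = 0.05,
                       tails = c("one", "two"),
                       design = c("paired", "two_sample")) {
  tails <- match.arg(tails)
  design <- match.arg(design)
  if (d == 0) abort_validation("`d` must be nonzero: target power is unattainable.")
  if (power <= 0 || power >= 1) abort_validation("`power` must be in (0, 1).")
  d <- abs(d)
  pw <- function(n) power_t(d, n, alpha, tails, design)
  hi <- 2L
  while (pw(hi) < power) {
    hi <- hi * 2L
    if (hi > 1e7) abort_validation("target power unattainable below n = 1e7.")
  }
  lo <- max(2L, hi %/% 2L)
  while (lo < hi) {
    mid <- (lo + hi) %/% 2L
    if (pw(mid) >= power) hi <- mid else lo <- mid + 1L
  }
  hi
}

#' Minimal detectable effect size for a fixed design
#'
#' Sensitivity power analysis: the positive standardised effect that a design
#' with `n` observations detects with the target power, found by root finding
#' on `d` in (1e-6, 10] to tolerance 1e-6.
#'
#' @inheritParams power_t
#' @param power Target power; must exceed `alpha` for a solution to exist.
#' @return The minimal detectable effect size.
#' @export
detectable_d <- function(n, power = 0.80, alpha = 0.05,
                         tails = c("one", "two"),
                         design = c("paired", "two_sample")) {
  tails <- match.arg(tails)
  design <- match.arg(design)
  check_power_args(n, alpha)
  if (power <= alpha) {
    abort_validation("`power` must exceed `alpha`: no positive effect solves this.")
  }
  if (power >= 1) abort_validation("`power` must be < 1.")
  f <- function(d) power_t(d, n, alpha, tails, design) - power
  if (f(10) < 0) {
    abort_validation("no detectable effect size below d = 10 for this design.")
  }
  stats::uniroot(f, c(1e-6, 10), tol = 1e-6)$root
}

#' Proportion of an effect-size distribution a design can detect
#'
#' For each acceptable power level, computes the minimal detectable effect of
#' the design and the proportion of the absolute empirical effect-size
#' distribution at or above it — connecting a planned design to the effects
#' actually reported in the field.
#'
#' @param data A data frame of effects, or a numeric vector.
#' @param n Sample size of the planned design.
#' @param power_levels Power levels to tabulate.
#' @inheritParams power_t
#' @param es Effect column name when `data` is a data frame.
#' @return A tibble with columns `power`, `detectable_d`, `prop_detectable`.
#' @export
detectable_proportion <- function(data, n, power_levels = c(0.8, 0.9, 0.95),
                                  alpha = 0.05, tails = c("one", "two"),
                                  design = c("paired", "two_sample"),
                                  es = "yi") {
  tails <- match.arg(tails)
  design <- match.arg(design)
  v <- abs(pull_effects(data, es))
  purrr::map(power_levels, function(p) {
    dd <- detectable_d(n, p, alpha, tails, design)
    tibble::tibble(
      power = p,
      detectable_d = dd,
      prop_detectable = sesoi_split(v, dd, absolute = TRUE)$prop_at_or_above
    )
  }) |> dplyr::bind_rows()
}
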