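#' Random-effects meta-analysis (DerSimonian–Laird)
#'
#' Pools study-level effects under the additive random-effects model
#' `y_i ~ N(mu, s_i^2 + tau^2)`. The between-study variance is the
#' closed-form DerSimonian–Laird moment estimator: with fixed-effect weights
#' `w_i = 1 / s_i^2`, `Q = sum w_i (y_i - y_FE)^2` and
#' `tau^2 = max(0, (Q - (k - 1)) / (sum w - sum w^2 / sum w))`; the pooled
#' effect then uses weights `1 / (s_i^2 + tau^2)`.
#'
#' @param data A data frame with effect and SE columns, or a numeric vector
#'   of effects (then `se` must be the numeric vector of standard errors).
#' @param es,se Column names (data-frame input) or the SE vector (numeric
#'   input).
#' @param level Confidence level for the normal-quantile CI.
#' @return An object of class `re_fit`: list with `mu`, `se_mu`, `ci_low`,
#'   `ci_high`, `tau2`, `Q`, `k`, `level`.
#' @examples
#' fit_random_effects(data.frame(yi = c(0.1, 0.3, 0.5),
#'                               sei = c(0.1, 0.2, 0.3)))
#' @export
fit_random_effects <- function(data, es = "yi", se = "sei", level = 0.95) {
  v <- extract_es_se(data, es, se)
  y <- v$y
  s <- v$s
  k <- length(y)
  if (k < 2) abort_validation("random-effects fit needs at least 2 studies.")
  w <- 1 / s^2
  y_fe <- sum(w * y) / sum(w)
  q <- sum(w * (y - y_fe)^2)
  c_dl <- sum(w) - sum(w^2) / sum(w)
  tau2 <- max(0, (q - (k - 1)) / c_dl)
  ws <- 1 / (s^2 + tau2)
  mu <- sum(ws * y) / sum(ws)
  se_mu <- sqrt(1 / sum(ws))
  z <- stats::qnorm(1 - (1 - level) / 2)
  structure(
    list(mu = mu, se_mu = se_mu,
         ci_low = mu - z * se_mu, ci_high = mu + z * se_mu,
         tau2 = tau2, Q = q, k = k, level = level),
    class = "re_fit"
  )
}

extract_es_se <- function(data, es, se) {
  if (is.data.frame(data)) {
    for (col in c(es, se)) {
      if (!col %in% names(data)) {
        abort_validation(sprintf("column `%s` not found.", col))
      }
    }
    y <- as.numeric(data[[es]])
    s <- as.numeric(data[[se]])
    id <- if ("study_id" %in% names(data)) as.character(data$study_id) else NULL
  } else {
    y <- as.numeric(data)
    s <- as.numeric(se)
    id <- NULL
  }
  if (length(y) != length(s)) {
    abort_validation("effects and standard errors differ in length.")
  }
  if (any(!is.finite(y)) || any(!is.finite(s)) || any(s <= 0)) {
    abort_validation("effects must be finite and standard errors finite and > 0.")
  }
  list(y = y, s = s, id = id)
}

#' @export
print.re_fit <- function(x, digits = 4, ...) {
  cat(sprintf(
    "Random-effects meta-analysis (DerSimonian-Laird), k = %d\n", x$k
  ))
  cat(sprintf("  mu = %.*f [%.*f, %.*f], tau^2 = %.*f, Q = %.*f\n",
              digits, x$mu, digits, x$ci_low, digits, x$ci_high,
              digits, x$tau2, digits, x$Q))
  invisible(x)
}

#' @exportS3Method generics::glance
glance.re_fit <- function(x, ...) {
  tibble::tibble(
    mu = x$mu, se_mu = x$se_mu, ci_low = x$ci_low, ci_high = x$ci_high,
    tau2 = x$tau2, Q = x$Q, k = x$k
  )
}

#' Limit meta-analysis: small-study-effect adjustment with shrunken estimates
#'
#' Extends the random-effects model with a small-study-effect parameter,
#' fitted on the generalised radial (Galbraith) plot. With
#' `tau^2` from [fit_random_effects()], each study contributes the
#' coordinates `x_i = 1 / sqrt(s_i^2 + tau^2)` (precision) and
#' `z_i = y_i / sqrt(s_i^2 + tau^2)` (standardised effect); ordinary least
#' squares of `z` on `x` gives the intercept `alpha` (the small-study
#' effect) and slope `beta` (the limit effect — the effect an infinitely
#' precise study would show). Each observed effect is then shrunk toward the
#' limit,
#' `y_i~ = beta + tau (y_i - beta) / sqrt(s_i^2 + tau^2)`,
#' yielding the bias-adjusted effect-size distribution. The adjusted summary
#' effect is `beta + tau alpha` (the expectation of the limit model), with a
#' delta-method CI from the coefficient covariance under the radial
#' construction's unit residual variance, treating `tau` as fixed.
#'
#' @inheritParams fit_random_effects
#' @return An object of class `limitmeta_fit`: `alpha`, `beta`, `tau2`,
#'   `tau`, `shrunken` (adjusted per-study effects, input order),
#'   `adjusted` and `unadjusted` one-row tibbles (`estimate`, `ci_low`,
#'   `ci_high`), the underlying `re_fit`, and the input `data`.
#' @export
fit_limit_meta <- function(data, es = "yi", se = "sei", level = 0.95) {
  v <- extract_es_se(data, es, se)
  y <- v$y
  s <- v$s
  k <- length(y)
  if (k < 3) {
    abort_validation("limit meta-analysis needs at least 3 studies.")
  }
  re <- fit_random_effects(y, se = s, level = level)
  tau2 <- re$tau2
  tau <- sqrt(tau2)
  prec <- 1 / sqrt(s^2 + tau2)
  if (max(prec) - min(prec) <= 1e-10) {
    abort_validation(paste(
      "all standard errors are (numerically) equal: the radial regression is",
      "degenerate and the small-study-effect adjustment is unidentifiable."
    ))
  }
  z <- y * prec
  coefs <- stats::coef(stats::lm(z ~ prec))
  alpha <- unname(coefs[1])
  beta <- unname(coefs[2])

  # coefficient covariance with residual variance fixed at 1 (radial model)
  xtx <- matrix(c(k, sum(prec), sum(prec), sum(prec^2)), 2, 2)
  vc <- solve(xtx)

  shrunken <- beta + tau * (y - beta) * prec
  zq <- stats::qnorm(1 - (1 - level) / 2)
  adj <- beta + tau * alpha
  var_adj <- vc[2, 2] + tau2 * vc[1, 1] + 2 * tau * vc[1, 2]
  structure(
    list(
      alpha = alpha, beta = beta, tau2 = tau2, tau = tau,
      Q = re$Q, k = k,
      shrunken = shrunken,
      adjusted = tibble::tibble(
        estimate = adj,
        ci_low = adj - zq * sqrt(var_adj),
        ci_high = adj + zq * sqrt(var_adj)
      ),
      unadjusted = tibble::tibble(
        estimate = re$mu, ci_low = re$ci_low, ci_high = re$ci_high
      ),
      vcov = vc,
      re = re,
      level = level,
      data = tibble::tibble(
        study_id = v$id %||% paste0("study_", seq_len(k)),
        yi = y, sei = s
      )
    ),
    class = "limitmeta_fit"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.limitmeta_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Limit meta-analysis, k = %d\n", x$k))
  cat(sprintf("  small-study effect alpha = %.*f, limit effect beta = %.*f, tau^2 = %.*f\n",
              digits, x$alpha, digits, x$beta, digits, x$tau2))
  cat(sprintf("  unadjusted summary: %.*f [%.*f, %.*f]\n",
              digits, x$unadjusted$estimate, digits, x$unadjusted$ci_low,
              digits, x$unadjusted$ci_high))
  cat(sprintf("  adjusted summary:   %.*f [%.*f, %.*f]\n",
              digits, x$adjusted$estimate, digits, x$adjusted$ci_low,
              digits, x$adjusted$ci_high))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.limitmeta_fit <- function(x, ...) {
  tibble::tibble(
    study_id = x$data$study_id,
    yi = x$data$yi,
    sei = x$data$sei,
    yi_adjusted = x$shrunken
  )
}

#' @exportS3Method generics::glance
glance.limitmeta_fit <- function(x, ...) {
  tibble::tibble(
    alpha = x$alpha, beta = x$beta, tau2 = x$tau2, Q = x$Q, k = x$k,
    adjusted = x$adjusted$estimate,
    adjusted_low = x$adjusted$ci_low, adjusted_high = x$adjusted$ci_high,
    unadjusted = x$unadjusted$estimate,
    unadjusted_low = x$unadjusted$ci_low, unadjusted_high = x$unadjusted$ci_high
  )
}

#' Benchmarks before and after publication-bias adjustment
#'
#' Pairs the raw benchmark row with the benchmarks of the limit-meta-adjusted
#' (shrunken) effect-size distribution. The adjustment always operates on
#' signed effects; when `absolute = TRUE` the conversion to magnitudes is
#' applied after shrinking, to both rows. Effect counts are identical between
#' rows by construction.
#'
#' @inheritParams esd_table
#' @return A tibble of class `esd_benchmarks_pba` with a `distribution`
#'   column (`"raw"`, `"adjusted"`) followed by the benchmark columns; the
#'   `limitmeta_fit` is attached as attribute `fit`.
#' @export
esd_table_pba <- function(data, es = "yi", se = "sei",
                          method = c("quads", "thirds"),
                          absolute = FALSE, weighted = FALSE, ci = FALSE,
                          n_boot = 2000, seed = NULL, level = 0.95,
                          bowley = FALSE) {
  method <- match.arg(method)
  data <- esd_data(data, es = es, se = se)
  fit <- fit_limit_meta(data)
  adjusted <- data
  adjusted$yi <- fit$shrunken
  seed2 <- if (is.null(seed)) NULL else as.integer(seed) + 1L
  raw_tab <- esd_table(data, method = method, absolute = absolute,
                       weighted = weighted, ci = ci, n_boot = n_boot,
                       seed = seed, level = level, bowley = bowley)
  adj_tab <- esd_table(adjusted, method = method, absolute = absolute,
                       weighted = weighted, ci = ci, n_boot = n_boot,
                       seed = seed2, level = level, bowley = bowley)
  pair <- dplyr::bind_rows(
    dplyr::mutate(tibble::as_tibble(raw_tab), distribution = "raw"),
    dplyr::mutate(tibble::as_tibble(adj_tab), distribution = "adjusted")
  )
  pair <- dplyr::relocate(dplyr::select(pair, -"group"), "distribution")
  structure(pair,
    method = method, probs = benchmark_probs(method), absolute = absolute,
    weighted = weighted, ci = ci, fit = fit, data = data,
    class = c("esd_benchmarks_pba", class(tibble::tibble()))
  )
}

#' @export
print.esd_benchmarks_pba <- function(x, digits = 2, ...) {
  probs <- attr(x, "probs", exact = TRUE)
  cat(sprintf(
    "Effect size benchmarks, raw vs. publication-bias adjusted (%s%% / %s%% / %s%% percentiles)\n",
    format(100 * probs[1]), format(100 * probs[2]), format(100 * probs[3])
  ))
  shown <- tibble::as_tibble(x)
  shown$distribution <- ifelse(shown$distribution == "raw",
                               "Raw effect size", "Adjusted effect size")
  print(round_benchmarks(shown, digits))
  invisible(x)
}
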