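# Independent oracles and fixture builders used across the suite.

# Small study-level fixture with duplicate study ids for dedup tests.
make_effects <- function() {
  tibble::tibble(
    study_id = c("A", "A", "B", "C", "C", "C"),
    yi = c(0.4, 0.3, 0.2, 0.3, -0.1, 0.5),
    sei = c(0.2, 0.1, 0.15, 0.1, 0.1, 0.3),
    group = c("g1", "g1", "g2", "g2", "g2", "g2"),
    n_total = c(40L, 40L, 30L, 25L, 25L, 25L)
  )
}

random_effect_frame <- function(k, seed) {
  withr::with_seed(seed, tibble::tibble(
    study_id = paste0("s", seq_len(k)),
    yi = stats::rnorm(k, 0.3, 0.3),
    sei = stats::runif(k, 0.05, 0.5)
  ))
}

# Replicate-expansion quantile oracle for integer weights: each value is
# repeated `w` times and the plain type-7 sample quantile is taken.
wq_expand_oracle <- function(x, w_int, p) {
  stats::quantile(rep(x, times = w_int), p, type = 7, names = FALSE)
}

# Loop-wise transliteration of the DerSimonian-Laird formulas, kept naive on
# purpose (scalar accumulation, no vectorisation shared with the package).
hand_dl <- function(y, s) {
  k <- length(y)
  sw <- 0; swy <- 0; sw2 <- 0
  for (i in seq_len(k)) {
    w <- 1 / s[i]^2
    sw <- sw + w; swy <- swy + w * y[i]; sw2 <- sw2 + w^2
  }
  yfe <- swy / sw
  q <- 0
  for (i in seq_len(k)) q <- q + (y[i] - yfe)^2 / s[i]^2
  tau2 <- max(0, (q - (k - 1)) / (sw - sw2 / sw))
  num <- 0; den <- 0
  for (i in seq_len(k)) {
    w <- 1 / (s[i]^2 + tau2)
    num <- num + w * y[i]; den <- den + w
  }
  list(mu = num / den, se_mu = sqrt(1 / den), tau2 = tau2, Q = q)
}

# Normal-equations solve of the generalised radial regression, independent of
# the package's lm() route: regress y_i/sqrt(s_i^2+tau2) on 1/sqrt(s_i^2+tau2).
radial_normal_equations <- function(y, s, tau2) {
  x <- 1 / sqrt(s^2 + tau2)
  z <- y * x
  n <- length(y)
  sx <- sum(x); sxx <- sum(x^2); sz <- sum(z); sxz <- sum(x * z)
  det <- n * sxx - sx^2
  alpha <- (sxx * sz - sx * sxz) / det
  beta <- (n * sxz - sx * sz) / det
  list(alpha = alpha, beta = beta)
}

# Noncentral-t upper tail by quadrature over the chi-square mixing density:
# P(T_{df,ncp} > t) = E_W[ P(Z > t sqrt(W/df) - ncp) ], W ~ chi^2_df.
nct_power_quadrature <- function(d, n, alpha = 0.05) {
  df <- n - 1
  ncp <- d * sqrt(n)
  tc <- stats::qt(1 - alpha, df)
  stats::integrate(function(w) {
    stats::dchisq(w, df) * stats::pnorm(tc * sqrt(w / df) - ncp,
                                        lower.tail = FALSE)
  }, 0, Inf, rel.tol = 1e-10)$value
}

write_fixture_csv <- function(df, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "effects.csv")
  readr::write_csv(df, path, progress = FALSE)
  path
}
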