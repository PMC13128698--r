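test_that("DerSimonian-Laird fit matches the hand-computed 3-study example", {
  fit <- fit_random_effects(data.frame(yi = c(0.1, 0.3, 0.5),
                                       sei = c(0.1, 0.2, 0.3)))
  expect_equal(fit$Q, 2.1224489795918, tolerance = 1e-10)
  expect_equal(fit$tau2, 0.0021428571428571, tolerance = 1e-8)
  h <- hand_dl(c(0.1, 0.3, 0.5), c(0.1, 0.2, 0.3))
  expect_equal(fit$mu, h$mu, tolerance = 1e-12)
  expect_equal(fit$se_mu, h$se_mu, tolerance = 1e-12)
})

test_that("DL fit agrees with metafor and the naive formulas on random instances", {
  skip_if_not_installed("metafor")
  withr::with_seed(101, {
    for (i in 1:20) {
      k <- sample(2:10, 1)
      y <- rnorm(k, 0.2, 0.4)
      s <- runif(k, 0.05, 0.5)
      fit <- fit_random_effects(y, se = s)
      h <- hand_dl(y, s)
      expect_equal(fit$tau2, h$tau2, tolerance = 1e-10)
      expect_equal(fit$mu, h$mu, tolerance = 1e-10)
      expect_equal(fit$Q, h$Q, tolerance = 1e-10)
      m <- metafor::rma(yi = y, sei = s, method = "DL")
      expect_equal(fit$tau2, unname(m$tau2), tolerance = 1e-8)
      expect_equal(fit$mu, unname(as.numeric(m$b)), tolerance = 1e-8)
      expect_equal(fit$se_mu, unname(m$se), tolerance = 1e-8)
    }
  })
})

test_that("degenerate random-effects inputs are rejected or collapse cleanly", {
  expect_error(fit_random_effects(0.3, se = 0.1), class = "esd_validation_error")
  fit <- fit_random_effects(c(0.4, 0.4), se = c(0.1, 0.2))
  expect_equal(fit$tau2, 0)
  expect_equal(fit$mu, 0.4)
  expect_equal(fit$Q, 0)
})

test_that("radial regression coefficients match a normal-equations solve", {
  y <- c(0.8, 0.5, 0.3, 0.2)
  s <- c(0.4, 0.3, 0.2, 0.1)
  fit <- fit_limit_meta(data.frame(yi = y, sei = s))
  oracle <- radial_normal_equations(y, s, fit$tau2)
  expect_equal(fit$alpha, oracle$alpha, tolerance = 1e-10)
  expect_equal(fit$beta, oracle$beta, tolerance = 1e-10)
  # shrunken estimates follow the closed form at these coefficients
  expect_equal(fit$shrunken,
               fit$beta + fit$tau * (y - fit$beta) / sqrt(s^2 + fit$tau2),
               tolerance = 1e-12)
  expect_equal(fit$adjusted$estimate, fit$beta + fit$tau * fit$alpha)
})

test_that("limit-meta preconditions: k >= 3 and varying standard errors", {
  expect_error(fit_limit_meta(data.frame(yi = c(0.1, 0.2), sei = c(0.1, 0.2))),
               class = "esd_validation_error")
  expect_error(
    fit_limit_meta(data.frame(yi = c(0.1, 0.2, 0.3), sei = rep(0.2, 3))),
    "unidentifiable", class = "esd_validation_error"
  )
})

test_that("homogeneous data shrink completely to the limit effect", {
  # identical effects -> Q = 0 -> tau2 = 0 -> every shrunken estimate = beta
  d <- data.frame(yi = rep(0.35, 5), sei = c(0.1, 0.15, 0.2, 0.3, 0.4))
  fit <- fit_limit_meta(d)
  expect_equal(fit$tau2, 0)
  expect_equal(fit$shrunken, rep(fit$beta, 5))
})

test_that("shrinkage contracts toward beta with the per-study factor", {
  withr::with_seed(77, {
    for (i in 1:25) {
      k <- sample(3:30, 1)
      d <- data.frame(yi = rnorm(k, 0.3, 0.5), sei = runif(k, 0.05, 0.6))
      fit <- fit_limit_meta(d)
      # contraction: each estimate moves toward (never across) the limit
      # effect, scaled by tau / sqrt(s^2 + tau^2) in [0, 1]
      expect_true(all(abs(fit$shrunken - fit$beta) <=
                        abs(d$yi - fit$beta) + 1e-12))
      expect_equal(fit$shrunken - fit$beta,
                   (d$yi - fit$beta) * fit$tau / sqrt(d$sei^2 + fit$tau2),
                   tolerance = 1e-12)
      expect_true(all(sign(fit$shrunken - fit$beta) == sign(d$yi - fit$beta) |
                        fit$shrunken == fit$beta))
      expect_length(fit$shrunken, k)
    }
  })
})

test_that("in the infinite-heterogeneity limit the adjustment vanishes", {
  d <- data.frame(yi = c(0.8, 0.5, 0.3, 0.2), sei = c(0.4, 0.3, 0.2, 0.1))
  fit <- fit_limit_meta(d)
  tau_huge <- 1e6
  shr <- fit$beta + tau_huge * (d$yi - fit$beta) / sqrt(d$sei^2 + tau_huge^2)
  expect_equal(shr, d$yi, tolerance = 1e-6)
})

test_that("tidy returns per-study adjusted effects aligned with the input", {
  d <- data.frame(study_id = c("a", "b", "c", "d"),
                  yi = c(0.8, 0.5, 0.3, 0.2), sei = c(0.4, 0.3, 0.2, 0.1))
  fit <- fit_limit_meta(d)
  td <- tidy(fit)
  expect_equal(td$study_id, d$study_id)
  expect_equal(td$yi, d$yi)
  expect_equal(td$yi_adjusted, fit$shrunken)
})

test_that("paired raw/adjusted tables share counts and adjust before absolute", {
  withr::with_seed(12, {
    d <- data.frame(yi = rnorm(40, 0.3, 0.4), sei = runif(40, 0.05, 0.5))
  })
  pair <- esd_table_pba(d, absolute = TRUE)
  expect_equal(pair$distribution, c("raw", "adjusted"))
  expect_equal(pair$n_effects, c(40L, 40L))
  fit <- attr(pair, "fit")
  # adjusted row == benchmarks of |shrunken|, i.e. signed shrinkage first
  expect_equal(pair$medium[2], unname(quantile(abs(fit$shrunken), 0.5)))
  expect_equal(pair$medium[1], unname(quantile(abs(d$yi), 0.5)))
})

test_that("a zero-heterogeneity dataset yields an adjusted row at beta", {
  d <- data.frame(yi = rep(0.35, 5), sei = c(0.1, 0.15, 0.2, 0.3, 0.4))
  pair <- esd_table_pba(d)
  fit <- attr(pair, "fit")
  adj <- pair[pair$distribution == "adjusted", ]
  expect_equal(c(adj$small, adj$medium, adj$large), rep(fit$beta, 3))
})

test_that("an unbiased literature leaves the median nearly unadjusted", {
  sim <- simulate_literature(k = 400, mu = 0.2, tau = 0.1, selection = 0,
                             seed = 314)
  pair <- esd_table_pba(sim)
  expect_lt(abs(pair$medium[1] - pair$medium[2]), 0.05)
})
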