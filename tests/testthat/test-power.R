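test_that("noncentral-t power reproduces reference values", {
  # null case: one-tailed power at d = 0 equals alpha
  expect_equal(power_t(0, 20, tails = "one", design = "paired"), 0.05)
  expect_equal(power_t(0, 50, alpha = 0.10, tails = "one", design = "paired"),
               0.10)
  # base-R oracle
  expect_equal(
    power_t(0.4, 27, tails = "one", design = "paired"),
    power.t.test(n = 27, delta = 0.4, sd = 1, sig.level = 0.05,
                 type = "one.sample", alternative = "one.sided")$power,
    tolerance = 1e-9
  )
  # power.t.test drops the far-tail rejection region; subtract it before
  # comparing so the agreement is tight rather than loose
  far_tail <- pt(-qt(0.975, 58), 58, ncp = 0.5 * sqrt(15))
  expect_equal(
    power_t(0.5, 30, tails = "two", design = "two_sample") - far_tail,
    power.t.test(n = 30, delta = 0.5, sd = 1, sig.level = 0.05,
                 type = "two.sample", alternative = "two.sided")$power,
    tolerance = 1e-9
  )
})

test_that("power agrees with direct quadrature of the noncentral t", {
  for (d in c(0.2, 0.5, 0.8)) {
    for (n in c(10, 27, 60)) {
      expect_equal(power_t(d, n, tails = "one", design = "paired"),
                   nct_power_quadrature(d, n), tolerance = 1e-8)
    }
  }
  expect_gte(power_t(0.5, 27, tails = "one", design = "paired"), 0.80)
})

test_that("power is monotone in n and |d|; two tails cost power", {
  ns <- c(5, 10, 20, 40, 80)
  expect_true(all(diff(vapply(ns, function(n)
    power_t(0.4, n, tails = "one", design = "paired"), numeric(1))) > 0))
  ds <- c(0.1, 0.3, 0.5, 0.8)
  expect_true(all(diff(vapply(ds, function(d)
    power_t(d, 30, tails = "one", design = "paired"), numeric(1))) > 0))
  expect_lt(power_t(0.4, 30, tails = "two", design = "paired"),
            power_t(0.4, 30, tails = "one", design = "paired"))
})

test_that("required_n returns the minimal integer sample size", {
  n <- required_n(0.5, 0.80, tails = "one", design = "paired")
  expect_equal(n, 27)
  expect_gte(power_t(0.5, n, tails = "one", design = "paired"), 0.80)
  expect_lt(power_t(0.5, n - 1, tails = "one", design = "paired"), 0.80)
  # minimality holds across designs and targets
  withr::with_seed(8, {
    for (i in 1:10) {
      d <- runif(1, 0.2, 1.2)
      tgt <- runif(1, 0.5, 0.95)
      for (design in c("paired", "two_sample")) {
        n <- required_n(d, tgt, tails = "two", design = design)
        expect_gte(power_t(d, n, tails = "two", design = design), tgt)
        if (n > 2) {
          expect_lt(power_t(d, n - 1, tails = "two", design = design), tgt)
        }
      }
    }
  })
  expect_lte(required_n(1.0, 0.8), required_n(0.5, 0.8))
  expect_error(required_n(0, 0.8), class = "esd_validation_error")
})

test_that("detectable_d inverts the power function", {
  dd <- detectable_d(27, 0.648, tails = "one", design = "paired")
  expect_equal(dd, 0.4, tolerance = 1e-3)
  # round trip: the effect detectable at required_n(d) is at most d
  n <- required_n(0.5, 0.8, tails = "one", design = "paired")
  expect_lte(detectable_d(n, 0.8, tails = "one", design = "paired"), 0.5)
  # larger n -> strictly smaller detectable effect
  dds <- vapply(c(10, 20, 40, 80), function(n)
    detectable_d(n, 0.8, tails = "one", design = "paired"), numeric(1))
  expect_true(all(diff(dds) < 0))
  expect_error(detectable_d(20, 0.04, alpha = 0.05),
               class = "esd_validation_error")
})

test_that("detectable_proportion counts the reachable share of the ESD", {
  esd <- data.frame(yi = seq(0.1, 1.0, by = 0.1), sei = rep(0.1, 10))
  # pick n so that the detectable effect at 80% power is ~0.35
  tab <- detectable_proportion(esd, n = 52, power_levels = 0.8,
                               tails = "one", design = "paired")
  expect_equal(tab$detectable_d, 0.35, tolerance = 0.01)
  expect_equal(tab$prop_detectable, 0.7) # 0.4..1.0: seven of ten effects
  # boundary: power barely above alpha detects nearly everything
  tab2 <- detectable_proportion(esd, n = 52, power_levels = 0.051,
                                tails = "one", design = "paired")
  expect_gt(tab2$prop_detectable, 0.9)
  # all-zero ESD: nothing at or above a positive detectable effect
  zero <- data.frame(yi = rep(0, 5), sei = rep(0.1, 5))
  tab3 <- detectable_proportion(zero, n = 20, power_levels = 0.8,
                                tails = "one", design = "paired")
  expect_equal(tab3$prop_detectable, 0)
})
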