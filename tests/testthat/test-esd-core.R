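test_that("CSV ingestion preserves rows, order and values", {
  df <- tibble::tibble(yi = c(0.1, 0.2, 0.3), sei = c(0.1, 0.1, 0.1))
  path <- write_fixture_csv(df)
  ds <- read_effect_table(path)
  expect_s3_class(ds, "esd_data")
  expect_equal(nrow(ds), 3)
  expect_equal(ds$yi, df$yi)
  expect_equal(ds$sei, df$sei)
})

test_that("validation errors name the offending rows and columns", {
  path <- write_fixture_csv(
    tibble::tibble(yi = c(0.1, 0.2), sei = c(0.1, -0.1))
  )
  expect_error(read_effect_table(path), "row\\(s\\) 2",
               class = "esd_validation_error")
  expect_error(read_effect_table("does/not/exist.csv"), "not found",
               class = "esd_validation_error")
  path2 <- write_fixture_csv(tibble::tibble(g = 0.1, g_se = 0.1))
  expect_error(read_effect_table(path2), "`yi`",
               class = "esd_validation_error")
  ds <- read_effect_table(path2, column_map = c(es = "g", se = "g_se"))
  expect_equal(ds$yi, 0.1)
})

test_that("rows with missing effect or SE are rejected unless skipping is requested", {
  path <- write_fixture_csv(
    tibble::tibble(yi = c(0.1, NA, 0.3), sei = c(0.1, 0.1, 0.1))
  )
  expect_error(read_effect_table(path), "row\\(s\\) 2",
               class = "esd_validation_error")
  ds <- read_effect_table(path, skip_invalid = TRUE)
  expect_equal(nrow(ds), 2)
  rep <- conversion_report(ds)
  expect_equal(rep$n_in, 3L)
  expect_equal(rep$n_out, 2L)
  expect_match(rep$warnings, "dropped 1 row")
})

test_that("write/read round-trips all fields for finite decimal inputs", {
  df <- make_effects()
  path <- write_fixture_csv(df)
  ds <- read_effect_table(path)
  path2 <- file.path(dirname(path), "again.csv")
  write_effect_table(ds, path2)
  ds2 <- read_effect_table(path2)
  expect_identical(tibble::as_tibble(ds2), tibble::as_tibble(ds))
})

test_that("deduplication keeps the most precise effect, ties broken toward zero", {
  ds <- esd_data(make_effects())
  out <- dedupe_by_study(ds)
  # study A: smallest SE wins
  expect_equal(out$yi[out$study_id == "A"], 0.3)
  # study C: SE tie between 0.3 and -0.1 -> effect closest to zero
  expect_equal(out$yi[out$study_id == "C"], -0.1)
  expect_equal(nrow(out), 3)
  rep <- conversion_report(out)
  expect_equal(rep$n_in, 6L)
  expect_equal(rep$n_deduplicated, 3L)
  expect_equal(rep$n_out, rep$n_in - rep$n_deduplicated)
})

test_that("deduplication is idempotent, order-preserving, and a no-op on unique ids", {
  ds <- esd_data(make_effects())
  once <- dedupe_by_study(ds)
  twice <- dedupe_by_study(once)
  strip <- function(x) {
    x <- tibble::as_tibble(x)
    attr(x, "report") <- NULL
    x
  }
  expect_equal(strip(twice), strip(once))
  expect_equal(conversion_report(twice)$n_deduplicated, 0L)
  # kept records appear in their original input order
  expect_equal(once$study_id, c("A", "B", "C"))

  unique_ds <- esd_data(tibble::tibble(
    study_id = c("X", "Y"), yi = c(0.1, 0.2), sei = c(0.1, 0.2)
  ))
  out <- dedupe_by_study(unique_ds)
  expect_equal(conversion_report(out)$n_deduplicated, 0L)
  expect_equal(out$yi, unique_ds$yi)
})

test_that("an exact tie on SE and |effect| keeps the first record", {
  ds <- esd_data(tibble::tibble(
    study_id = c("A", "A"), yi = c(0.3, -0.3), sei = c(0.1, 0.1)
  ))
  out <- dedupe_by_study(ds)
  expect_equal(out$yi, 0.3)
})

test_that("rows without study ids are each their own study, with a warning", {
  ds <- esd_data(tibble::tibble(yi = c(0.1, 0.2), sei = c(0.1, 0.1)))
  expect_warning(out <- dedupe_by_study(ds), "own study")
  expect_equal(nrow(out), 2)
  expect_length(conversion_report(out)$warnings, 1)
})

test_that("absolute-value folding is exact, order-preserving and idempotent", {
  ds <- esd_data(tibble::tibble(yi = c(-0.3, 0.2), sei = c(0.1, 0.1)))
  out <- to_absolute(ds)
  expect_equal(out$yi, c(0.3, 0.2))
  expect_equal(out$sei, ds$sei)
  expect_equal(to_absolute(out)$yi, out$yi)
  nonneg <- esd_data(tibble::tibble(yi = c(0.1, 0.4), sei = c(0.1, 0.1)))
  expect_equal(to_absolute(nonneg)$yi, nonneg$yi)
})

test_that("Hedges correction follows J = 1 - 3/(4 df - 1) and contracts toward zero", {
  expect_equal(d_to_g(0, df = 18)$g, 0)
  expect_equal(d_to_g(1, df = 18)$g, 1 - 3 / 71)
  expect_equal(d_to_g(-0.5, df = 18)$g, -(0.5 * (1 - 3 / 71)))
  # sign symmetry and contraction over a grid
  d <- c(-2, -0.5, 0.3, 1.7)
  for (df in c(2, 5, 30, 200)) {
    g <- d_to_g(d, df)$g
    expect_equal(abs(d_to_g(-d, df)$g), abs(g))
    expect_true(all(abs(g) < abs(d)))
  }
  expect_equal(d_to_g(1, df = 18, se_d = 0.2)$se_g, 0.2 * (1 - 3 / 71))
  expect_error(d_to_g(1, df = 1), class = "esd_validation_error")
})

test_that("correlation conversion matches the closed form and rejects |r| >= 1", {
  expect_equal(r_to_d(0.5), 2 * 0.5 / sqrt(0.75))
  expect_equal(r_to_d(0), 0)
  expect_error(r_to_d(1), class = "esd_validation_error")
})
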