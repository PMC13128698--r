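#' Build a validated effect-size dataset
#'
#' Validates and canonicalises a table of study-level effect sizes — the
#' substrate for every other computation in the package. Each row is one
#' effect: a signed estimate `yi` in the units of its metric (Hedges' g by
#' default) and its standard error `sei`. Optional columns carry a study
#' identifier, a grouping label (e.g. clinical subgroup) and the total sample
#' size. Extra columns are kept untouched.
#'
#' @param data A data frame with one row per effect.
#' @param es,se Names of the effect-size and standard-error columns.
#' @param study,group,n_total Names of the optional study-id, grouping and
#'   total-sample-size columns; ignored when absent from `data`.
#' @param metric Label for the common effect-size metric of the records.
#' @return A tibble of class `esd_data` with canonical column names
#'   (`yi`, `sei`, and `study_id`/`group`/`n_total` when present) and a
#'   `metric` attribute. Input row order is preserved.
#' @examples
#' esd_data(data.frame(yi = c(0.2, -0.1), sei = c(0.1, 0.2)))
#' @export
esd_data <- function(data, es = "yi", se = "sei", study = "study_id",
                     group = "group", n_total = "n_total",
                     metric = "hedges_g") {
  if (!is.data.frame(data)) {
    abort_validation("`data` must be a data frame.")
  }
  if (nrow(data) == 0) {
    abort_validation("effect-size dataset must contain at least one row.")
  }
  for (col in c(es, se)) {
    if (!col %in% names(data)) {
      abort_validation(sprintf("column `%s` not found in the input table.", col))
    }
  }
  out <- tibble::as_tibble(data)
  out <- rename_role(out, es, "yi")
  out <- rename_role(out, se, "sei")
  if (study %in% names(out)) out <- rename_role(out, study, "study_id")
  if (group %in% names(out)) out <- rename_role(out, group, "group")
  if (n_total %in% names(out)) out <- rename_role(out, n_total, "n_total")

  validate_effect_columns(out)
  structure(out,
    metric = metric,
    class = c("esd_data", class(tibble::tibble()))
  )
}

rename_role <- function(data, from, to) {
  if (from != to) names(data)[names(data) == from] <- to
  data
}

validate_effect_columns <- function(data) {
  for (col in c("yi", "sei")) {
    if (!is.numeric(data[[col]])) {
      abort_validation(sprintf("column `%s` must be numeric.", col))
    }
  }
  bad <- which(!is.finite(data$yi))
  if (length(bad)) {
    abort_validation(sprintf(
      "missing or non-finite effect size in row(s) %s.", row_list(bad)
    ))
  }
  bad <- which(!is.finite(data$sei) | data$sei <= 0)
  if (length(bad)) {
    abort_validation(sprintf(
      "standard error must be finite and > 0; violated in row(s) %s.",
      row_list(bad)
    ))
  }
  if ("n_total" %in% names(data)) {
    bad <- which(!is.na(data$n_total) & data$n_total < 2)
    if (length(bad)) {
      abort_validation(sprintf(
        "`n_total` must be >= 2 when present; violated in row(s) %s.",
        row_list(bad)
      ))
    }
  }
  invisible(data)
}

row_list <- function(idx, max_show = 5) {
  shown <- paste(utils::head(idx, max_show), collapse = ", ")
  if (length(idx) > max_show) shown <- paste0(shown, ", ...")
  shown
}

abort_validation <- function(msg, ...) {
  rlang::abort(msg, class = "esd_validation_error", ...)
}

#' Read a study-level effect-size table from CSV
#'
#' Reads a comma-separated file (header row required, UTF-8, decimal point)
#' with one row per effect and validates it into an [esd_data] tibble. The
#' default column layout is `yi`, `sei`, `group`, `study_id`, `n_total`;
#' other layouts are mapped via `column_map`.
#'
#' Rows with a missing effect or standard error are an error by default, so
#' that nothing is dropped silently; with `skip_invalid = TRUE` they are
#' removed and counted in the ingestion report (see [conversion_report()]).
#'
#' @param path Path to a CSV file.
#' @param column_map Optional named character vector mapping semantic roles to
#'   column names, e.g. `c(es = "g", se = "g_se")`. Recognised roles:
#'   `es`, `se`, `study`, `group`, `n_total`.
#' @param skip_invalid Drop (and count) rows with missing effect/SE instead of
#'   erroring.
#' @param metric Metric label recorded on the returned dataset.
#' @return An [esd_data] tibble; the ingestion report is attached as the
#'   `report` attribute.
#' @export
read_effect_table <- function(path, column_map = NULL, skip_invalid = FALSE,
                              metric = "hedges_g") {
  if (!file.exists(path)) {
    abort_validation(sprintf("input file not found: %s", path))
  }
  roles <- c(es = "yi", se = "sei", study = "study_id",
             group = "group", n_total = "n_total")
  if (!is.null(column_map)) {
    unknown <- setdiff(names(column_map), names(roles))
    if (length(unknown)) {
      abort_validation(sprintf("unknown column_map role(s): %s",
                               paste(unknown, collapse = ", ")))
    }
    roles[names(column_map)] <- column_map
  }
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  for (role in c("es", "se")) {
    if (!roles[[role]] %in% names(raw)) {
      abort_validation(sprintf(
        "mapped %s column `%s` not found in %s.", role, roles[[role]], path
      ))
    }
  }
  for (col in c(roles[["es"]], roles[["se"]])) {
    if (!is.numeric(raw[[col]])) {
      abort_validation(sprintf("column `%s` in %s is not numeric.", col, path))
    }
  }

  warnings <- character()
  missing_rows <- which(is.na(raw[[roles[["es"]]]]) | is.na(raw[[roles[["se"]]]]))
  if (length(missing_rows)) {
    if (!skip_invalid) {
      abort_validation(sprintf(
        "missing effect size or standard error in row(s) %s (set skip_invalid = TRUE to drop them).",
        row_list(missing_rows)
      ))
    }
    warnings <- c(warnings, sprintf(
      "dropped %d row(s) with missing effect size or standard error (rows %s)",
      length(missing_rows), row_list(missing_rows)
    ))
    raw <- raw[-missing_rows, , drop = FALSE]
  }
  bad_se <- which(raw[[roles[["se"]]]] <= 0)
  if (length(bad_se)) {
    abort_validation(sprintf(
      "standard error must be > 0; violated in row(s) %s of %s.",
      row_list(bad_se), path
    ))
  }

  ds <- esd_data(raw, es = roles[["es"]], se = roles[["se"]],
                 study = roles[["study"]], group = roles[["group"]],
                 n_total = roles[["n_total"]], metric = metric)
  attr(ds, "report") <- new_report(
    n_in = nrow(raw) + length(missing_rows), n_out = nrow(raw),
    warnings = warnings
  )
  ds
}

#' Write an effect-size dataset back to CSV
#'
#' Inverse of [read_effect_table()]: writes the canonical column layout so a
#' filtered dataset round-trips bit-equal for finite decimal inputs.
#'
#' @param data An [esd_data] tibble (or plain data frame).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_effect_table <- function(data, path) {
  readr::write_csv(tibble::as_tibble(data), path, progress = FALSE)
  invisible(path)
}

new_report <- function(n_in, n_out, n_converted = 0L, warnings = character()) {
  list(
    n_in = as.integer(n_in),
    n_out = as.integer(n_out),
    n_converted = as.integer(n_converted),
    n_deduplicated = as.integer(n_in - n_out),
    warnings = warnings
  )
}

#' Retrieve the ingestion/filtering report of a dataset
#'
#' [read_effect_table()] and [dedupe_by_study()] attach a report recording how
#' many rows went in and out, how many were converted or deduplicated, and any
#' warnings. Serialise it with [jsonlite::toJSON()].
#'
#' @param data A dataset returned by those functions.
#' @return A list with elements `n_in`, `n_out`, `n_converted`,
#'   `n_deduplicated`, `warnings`, or `NULL` when no report is attached.
#' @export
conversion_report <- function(data) {
  attr(data, "report", exact = TRUE)
}

#' Keep one effect per study
#'
#' Reduces a raw multi-effect extraction to one effect per study: within each
#' `study_id` the record with the smallest standard error is kept; ties on the
#' standard error are broken by the effect closest to zero regardless of sign;
#' a remaining exact tie keeps the first record in input order. Input order of
#' the kept records is preserved, and the operation is idempotent.
#'
#' @param data An [esd_data] tibble. When no `study_id` column is present (or
#'   it is all missing), every row is treated as its own study and a warning
#'   is recorded in the report.
#' @return The deduplicated dataset with a filtering report attached
#'   (see [conversion_report()]).
#' @export
dedupe_by_study <- function(data) {
  n_in <- nrow(data)
  warnings <- character()
  if (!"study_id" %in% names(data) || all(is.na(data$study_id))) {
    warnings <- "no study identifiers: every row treated as its own study"
    rlang::warn(warnings)
    attr(data, "report") <- new_report(n_in, n_in, warnings = warnings)
    return(data)
  }
  keep <- tibble::as_tibble(data) |>
    dplyr::mutate(.row = dplyr::row_number()) |>
    dplyr::arrange(.data$sei, abs(.data$yi), .data$.row) |>
    dplyr::distinct(.data$study_id, .keep_all = TRUE) |>
    dplyr::arrange(.data$.row)
  out <- dplyr::select(keep, -".row")
  out <- structure(out,
    metric = attr(data, "metric", exact = TRUE),
    class = c("esd_data", class(tibble::tibble()))
  )
  attr(out, "report") <- new_report(n_in, nrow(out), warnings = warnings)
  out
}

#' Fold a dataset to absolute effect sizes
#'
#' Replaces every effect size by its magnitude, leaving standard errors and
#' row order untouched. Used for benchmarks and plots of the absolute
#' effect-size distribution; idempotent.
#'
#' @param data An [esd_data] tibble (or any data frame with a `yi` column).
#' @return The dataset with `yi = |yi|`.
#' @export
to_absolute <- function(data) {
  data$yi <- abs(data$yi)
  data
}

#' Convert Cohen's d to Hedges' g
#'
#' Applies the standard small-sample bias correction
#' `J = 1 - 3 / (4 df - 1)`, giving `g = J d` (and `se_g = J se_d` when a
#' standard error is supplied). Use `df = n1 + n2 - 2` for two-sample designs
#' and `df = n - 1` for paired or one-sample designs. The correction always
#' contracts toward zero: `|g| < |d|` for nonzero `d`.
#'
#' @param d Cohen's d (vectorised).
#' @param df Degrees of freedom, `>= 2`.
#' @param se_d Optional standard error of `d`.
#' @return A tibble with columns `g` and `se_g` (`NA` when `se_d` is absent).
#' @examples
#' d_to_g(1, df = 18) # g = 1 - 3/71
#' @export
d_to_g <- function(d, df, se_d = NULL) {
  if (any(!is.finite(df)) || any(df < 2)) {
    abort_validation("`df` must be >= 2.")
  }
  j <- 1 - 3 / (4 * df - 1)
  tibble::tibble(
    g = d * j,
    se_g = if (is.null(se_d)) NA_real_ else se_d * j
  )
}

#' Convert Pearson's r to Cohen's d
#'
#' Explicit opt-in conversion `d = 2 r / sqrt(1 - r^2)` for correlation-metric
#' records; chain with [d_to_g()] to reach Hedges' g.
#'
#' @param r Correlations in (-1, 1).
#' @return Numeric vector of Cohen's d values.
#' @export
r_to_d <- function(r) {
  if (any(!is.finite(r)) || any(abs(r) >= 1)) {
    abort_validation("`r` must lie strictly inside (-1, 1).")
  }
  2 * r / sqrt(1 - r^2)
}
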