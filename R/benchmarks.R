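#' Quantile levels for a benchmark method
#'
#' "quads" labels small/medium/large effects at the 25th, 50th and 75th
#' percentiles of the distribution; "thirds" uses the 16.65th, 50th and
#' 83.35th percentiles, which cut the distribution into three equal-mass
#' ranges around conventional rounding.
#'
#' @param method `"quads"` or `"thirds"`.
#' @return Numeric triple of probabilities.
#' @export
benchmark_probs <- function(method = c("quads", "thirds")) {
  method <- match.arg(method)
  switch(method,
    quads = c(0.25, 0.50, 0.75),
    thirds = c(0.1665, 0.50, 0.8335)
  )
}

#' Field-specific effect-size benchmarks
#'
#' The central table operation: estimates small/medium/large effect-size
#' benchmarks as quantiles of the empirical effect-size distribution, overall
#' and (optionally) per group. Options mirror common meta-analytic practice:
#' inverse-variance weighting (`1 / sei^2`), absolute effect sizes,
#' percentile-bootstrap confidence intervals, and Bowley skewness as a
#' robustness diagnostic. Groups with fewer than `min_group_n` effects are
#' omitted from the table; an overall row labelled `"All"` is always
#' appended.
#'
#' @param data A data frame or [esd_data] tibble of study-level effects.
#' @param es,se Effect-size and standard-error column names.
#' @param group Optional grouping column name; `NULL` for an overall-only
#'   table.
#' @param method Benchmark quantiles: `"quads"` (25/50/75) or `"thirds"`
#'   (16.65/50/83.35).
#' @param min_group_n Minimum effects a group needs to be reported
#'   (default 3).
#' @param absolute Compute benchmarks on absolute effect sizes.
#' @param weighted Weight quantiles by inverse variance (requires `se`).
#' @param ci Add percentile-bootstrap 95% CIs (requires `seed`).
#' @param n_boot Bootstrap replicates per benchmark (default 2000).
#' @param seed Integer seed for the bootstrap; resampling is per group.
#' @param level Confidence level for the bootstrap interval.
#' @param bowley Add Bowley's skewness coefficient per row.
#' @return A tibble of class `esd_benchmarks` with columns `group`, `small`,
#'   `medium`, `large`, `n_effects` (plus `*_low`/`*_high` CI columns and
#'   `bowley` when requested). Attributes record the method, probabilities
#'   and flags; `attr(, "data")` keeps the input for [ggplot2::autoplot()].
#' @examples
#' d <- data.frame(yi = seq(-0.2, 1, by = 0.1), sei = rep(0.1, 13))
#' esd_table(d)
#' @export
esd_table <- function(data, es = "yi", se = "sei", group = NULL,
                      method = c("quads", "thirds"), min_group_n = 3,
                      absolute = FALSE, weighted = FALSE, ci = FALSE,
                      n_boot = 2000, seed = NULL, level = 0.95,
                      bowley = FALSE) {
  method <- match.arg(method)
  probs <- benchmark_probs(method)
  data <- esd_data(data, es = es, se = se)
  if (weighted && any(is.na(data$sei))) {
    abort_validation("`weighted = TRUE` requires a standard error for every effect.")
  }
  if (ci && is.null(seed)) {
    abort_validation("`ci = TRUE` requires an integer `seed`.")
  }
  if (!is.null(group) && !group %in% names(data)) {
    abort_validation(sprintf("grouping column `%s` not found.", group))
  }

  values_of <- function(d) if (absolute) abs(d$yi) else d$yi
  weights_of <- function(d) if (weighted) 1 / d$sei^2 else NULL

  one_row <- function(d, label, row_seed) {
    v <- values_of(d)
    w <- weights_of(d)
    q <- esd_quantile(v, probs, w)
    row <- tibble::tibble(
      group = label,
      small = q[1], medium = q[2], large = q[3],
      n_effects = length(v)
    )
    if (ci) {
      b <- bootstrap_quantile_ci(v, probs, n_boot = n_boot, seed = row_seed,
                                 level = level, weights = w)
      row$small_low <- b$low[1]; row$small_high <- b$high[1]
      row$medium_low <- b$low[2]; row$medium_high <- b$high[2]
      row$large_low <- b$low[3]; row$large_high <- b$high[3]
    }
    if (bowley) {
      row$bowley <- tryCatch(bowley_skewness(v, w),
                             esd_validation_error = function(e) NA_real_)
    }
    row
  }

  rows <- list()
  if (!is.null(group)) {
    labels <- unique(as.character(data[[group]]))
    labels <- labels[!is.na(labels)]
    kept <- 0L
    for (i in seq_along(labels)) {
      d <- data[!is.na(data[[group]]) & as.character(data[[group]]) == labels[i], ]
      if (nrow(d) < min_group_n) next
      kept <- kept + 1L
      rows[[length(rows) + 1L]] <-
        one_row(d, labels[i], if (ci) as.integer(seed) + i else NULL)
    }
    if (kept == 0L) {
      abort_validation(sprintf(
        "no group reaches min_group_n = %d effects; benchmark table would be empty.",
        min_group_n
      ))
    }
  }
  rows[[length(rows) + 1L]] <-
    one_row(data, "All", if (ci) as.integer(seed) else NULL)
  out <- dplyr::bind_rows(rows)

  structure(out,
    method = method, probs = probs, absolute = absolute, weighted = weighted,
    ci = ci, level = level, min_group_n = min_group_n,
    data = data,
    class = c("esd_benchmarks", class(tibble::tibble()))
  )
}

#' @export
print.esd_benchmarks <- function(x, digits = 2, ...) {
  probs <- attr(x, "probs", exact = TRUE)
  cat(sprintf(
    "Effect size benchmarks (%s: %s%% / %s%% / %s%% percentiles%s%s)\n",
    attr(x, "method", exact = TRUE),
    format(100 * probs[1]), format(100 * probs[2]), format(100 * probs[3]),
    if (isTRUE(attr(x, "absolute", exact = TRUE))) ", absolute" else "",
    if (isTRUE(attr(x, "weighted", exact = TRUE))) ", inverse-variance weighted" else ""
  ))
  print(round_benchmarks(x, digits))
  invisible(x)
}

round_benchmarks <- function(x, digits = 2) {
  out <- tibble::as_tibble(x)
  num <- vapply(out, is.numeric, logical(1)) & names(out) != "n_effects"
  out[num] <- lapply(out[num], round, digits = digits)
  out
}

#' Render a benchmark table as markdown, CSV or JSON
#'
#' Tables render to 2 decimal places; the underlying tibble keeps full
#' precision.
#'
#' @param x An `esd_benchmarks` (or adjusted-pair) tibble.
#' @param format `"markdown"`, `"csv"` or `"json"`.
#' @param path Optional file to write to.
#' @param digits Decimal places for markdown rendering.
#' @return The rendered text (character scalar), invisibly when written to
#'   `path`.
#' @export
format_benchmarks <- function(x, format = c("markdown", "csv", "json"),
                              path = NULL, digits = 2) {
  format <- match.arg(format)
  tab <- tibble::as_tibble(x)
  text <- switch(format,
    markdown = markdown_table(round_benchmarks(x, digits)),
    csv = readr::format_csv(tab),
    json = as.character(jsonlite::toJSON(tab, digits = NA, na = "null"))
  )
  if (!is.null(path)) {
    writeLines(text, path)
    return(invisible(text))
  }
  text
}

markdown_table <- function(df) {
  cells <- rbind(names(df), vapply(df, function(col) format(col, trim = TRUE),
                                   character(nrow(df))))
  cells <- matrix(as.character(cells), nrow = nrow(df) + 1)
  widths <- apply(nchar(cells), 2, max)
  pad <- function(row) paste0(
    "| ", paste(mapply(formatC, row, width = widths, flag = "-"),
                collapse = " | "), " |"
  )
  sep <- paste0("|", paste(vapply(widths + 2, function(w)
    paste(rep("-", w), collapse = ""), character(1)), collapse = "|"), "|")
  lines <- c(pad(cells[1, ]), sep,
             vapply(seq_len(nrow(df)), function(i) pad(cells[i + 1, ]),
                    character(1)))
  paste(lines, collapse = "\n")
}

#' @exportS3Method generics::tidy
tidy.esd_benchmarks <- function(x, ...) {
  probs <- attr(x, "probs", exact = TRUE)
  tab <- tibble::as_tibble(x)
  has_ci <- "small_low" %in% names(tab)
  levels <- c("small", "medium", "large")
  rows <- purrr::map(levels, function(b) {
    out <- tibble::tibble(
      group = tab$group,
      benchmark = b,
      prob = probs[match(b, levels)],
      estimate = tab[[b]],
      n_effects = tab$n_effects
    )
    if (has_ci) {
      out$ci_low <- tab[[paste0(b, "_low")]]
      out$ci_high <- tab[[paste0(b, "_high")]]
    }
    if ("bowley" %in% names(tab)) out$bowley <- tab$bowley
    out
  })
  out <- dplyr::bind_rows(rows)
  out[order(match(out$group, tab$group), match(out$benchmark, levels)), ]
}

#' @exportS3Method generics::glance
glance.esd_benchmarks <- function(x, ...) {
  overall <- tibble::as_tibble(x)[x$group == "All", , drop = FALSE]
  tibble::tibble(
    method = attr(x, "method", exact = TRUE),
    absolute = isTRUE(attr(x, "absolute", exact = TRUE)),
    weighted = isTRUE(attr(x, "weighted", exact = TRUE)),
    n_groups = sum(x$group != "All"),
    n_effects = overall$n_effects[1],
    median = overall$medium[1],
    bowley = if ("bowley" %in% names(overall)) overall$bowley[1] else NA_real_
  )
}
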