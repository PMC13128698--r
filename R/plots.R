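#' Histogram bins aligned to zero
#'
#' Bins effect sizes into half-open intervals `[edge, edge + bin_width)`
#' anchored at zero, so a value exactly on an edge falls in the upper bin.
#' A small relative tolerance guards against decimal values (e.g. 0.3 with
#' width 0.1) landing one bin low through floating-point representation.
#'
#' @param x Numeric vector.
#' @param bin_width Positive bin width in effect-size units.
#' @return A tibble with `bin_left`, `bin_right`, `count`, covering the full
#'   occupied range contiguously; counts sum to `length(x)`.
#' @export
esd_bins <- function(x, bin_width = 0.1) {
  if (bin_width <= 0) abort_validation("`bin_width` must be > 0.")
  if (length(x) == 0) abort_validation("`x` must be non-empty.")
  idx <- floor(x / bin_width + 1e-9)
  rng <- seq(min(idx), max(idx))
  counts <- as.integer(table(factor(idx, levels = rng)))
  tibble::tibble(
    bin_left = rng * bin_width,
    bin_right = (rng + 1) * bin_width,
    count = counts
  )
}

esd_theme <- function() {
  ggplot2::theme_minimal(base_size = 11) +
    ggplot2::theme(panel.grid.minor = ggplot2::element_blank())
}

finish_plot <- function(p, manifest, path) {
  attr(p, "esd_manifest") <- manifest
  if (!is.null(path)) {
    ggplot2::ggsave(path, plot = p, width = 7, height = 4.5, dpi = 150)
    attr(p, "esd_manifest")$path <- path
  }
  p
}

#' Machine-readable manifest of a plot
#'
#' Every plotting function attaches a manifest — bin edges and counts, line
#' positions, proportions, diamond coordinates — so tests and downstream code
#' can assert plot content without comparing pixels.
#'
#' @param p A ggplot returned by one of the `plot_*()` functions.
#' @return The manifest list, or `NULL`.
#' @export
plot_manifest <- function(p) {
  attr(p, "esd_manifest", exact = TRUE)
}

#' Histogram of an effect-size distribution
#'
#' @param data A data frame of effects (column `es`) or a numeric vector.
#' @param bin_width Bin width in effect-size units (default 0.1).
#' @param absolute Plot magnitudes instead of signed effects.
#' @param es_label Axis label for the effect-size metric.
#' @param path Optional output file (`.png`, `.svg` or `.pdf`); written with
#'   [ggplot2::ggsave()].
#' @param es Effect column name when `data` is a data frame.
#' @return A ggplot; its manifest (see [plot_manifest()]) lists `bin_width`,
#'   `bin_left`, `bin_right`, `counts` and `n`.
#' @export
plot_esd <- function(data, bin_width = 0.1, absolute = FALSE,
                     es_label = "Hedges' g", path = NULL, es = "yi") {
  v <- pull_effects(data, es)
  if (absolute) v <- abs(v)
  bins <- esd_bins(v, bin_width)
  p <- ggplot2::ggplot(bins) +
    ggplot2::geom_col(
      ggplot2::aes(x = (.data$bin_left + .data$bin_right) / 2, y = .data$count),
      width = bin_width, fill = "#9ecae1", colour = "white"
    ) +
    ggplot2::labs(x = es_label, y = "Number of effects") +
    esd_theme()
  finish_plot(p, list(
    kind = "esd", bin_width = bin_width, absolute = absolute,
    bin_left = bins$bin_left, bin_right = bins$bin_right,
    counts = bins$count, n = length(v)
  ), path)
}

#' Effect-size distribution with benchmark lines and CI ribbons
#'
#' Draws the (by default absolute) distribution with vertical lines at the
#' small/medium/large benchmarks and, when `ci = TRUE`, shaded percentile
#' bootstrap interval bands around each line; the three values are annotated
#' to two decimals.
#'
#' @inheritParams plot_esd
#' @inheritParams esd_table
#' @return A ggplot; the manifest adds `benchmarks` (line positions) and,
#'   with `ci`, `ci_low`/`ci_high`.
#' @export
plot_esd_benchmarks <- function(data, method = c("quads", "thirds"),
                                ci = FALSE, n_boot = 2000, seed = NULL,
                                bin_width = 0.1, absolute = TRUE,
                                weighted = FALSE,
                                es_label = "Hedges' g", path = NULL,
                                es = "yi", se = "sei") {
  method <- match.arg(method)
  tab <- esd_table(data, es = es, se = se, method = method,
                   absolute = absolute, weighted = weighted,
                   ci = ci, n_boot = n_boot, seed = seed)
  bench <- c(tab$small[1], tab$medium[1], tab$large[1])
  v <- pull_effects(data, es)
  if (absolute) v <- abs(v)
  bins <- esd_bins(v, bin_width)
  p <- ggplot2::ggplot(bins) +
    ggplot2::geom_col(
      ggplot2::aes(x = (.data$bin_left + .data$bin_right) / 2, y = .data$count),
      width = bin_width, fill = "#9ecae1", colour = "white"
    )
  manifest <- list(
    kind = "benchmarks", method = method, bin_width = bin_width,
    absolute = absolute,
    bin_left = bins$bin_left, bin_right = bins$bin_right,
    counts = bins$count, n = length(v), benchmarks = bench
  )
  if (ci) {
    band <- tibble::tibble(
      low = c(tab$small_low[1], tab$medium_low[1], tab$large_low[1]),
      high = c(tab$small_high[1], tab$medium_high[1], tab$large_high[1])
    )
    p <- p + ggplot2::geom_rect(
      data = band,
      ggplot2::aes(xmin = .data$low, xmax = .data$high,
                   ymin = 0, ymax = Inf),
      fill = "red", alpha = 0.15, inherit.aes = FALSE
    )
    manifest$ci_low <- band$low
    manifest$ci_high <- band$high
  }
  p <- p +
    ggplot2::geom_vline(xintercept = bench, linetype = "dashed",
                        colour = "grey30") +
    ggplot2::annotate(
      "text", x = bench, y = Inf, vjust = 1.5, hjust = -0.1, size = 3,
      label = sprintf("%.2f", bench)
    ) +
    ggplot2::labs(x = es_label, y = "Number of effects") +
    esd_theme()
  finish_plot(p, manifest, path)
}

#' Distribution split at a smallest effect size of interest
#'
#' Two-colour histogram of the absolute effect-size distribution: effects
#' below the SESOI in light blue, effects at or above it in dark blue, with
#' the two percentages annotated. A bin straddling the SESOI is split at the
#' exact value, so the colours always reflect the true proportions.
#'
#' @inheritParams plot_esd
#' @param sesoi Smallest effect size of interest.
#' @return A ggplot; the manifest adds `sesoi`, `prop_below`,
#'   `prop_at_or_above`, and per-segment columns `seg_left`, `seg_right`,
#'   `seg_count`, `seg_above`.
#' @export
plot_sesoi <- function(data, sesoi, bin_width = 0.1,
                       es_label = "Hedges' g", path = NULL, es = "yi") {
  v <- abs(pull_effects(data, es))
  split <- sesoi_split(v, sesoi, absolute = TRUE)
  idx <- floor(v / bin_width + 1e-9)
  above <- v >= sesoi
  seg <- tibble::tibble(idx = idx, above = above) |>
    dplyr::count(.data$idx, .data$above, name = "count") |>
    dplyr::mutate(
      bin_left = .data$idx * bin_width,
      bin_right = (.data$idx + 1) * bin_width,
      seg_left = ifelse(.data$above, pmax(.data$bin_left, sesoi), .data$bin_left),
      seg_right = ifelse(.data$above, .data$bin_right,
                         pmin(.data$bin_right, sesoi))
    )
  p <- ggplot2::ggplot(seg) +
    ggplot2::geom_col(
      ggplot2::aes(x = (.data$bin_left + .data$bin_right) / 2,
                   y = .data$count, fill = .data$above),
      width = bin_width, colour = "white"
    ) +
    ggplot2::scale_fill_manual(
      values = c(`FALSE` = "#9ecae1", `TRUE` = "#08519c"),
      labels = c(`FALSE` = sprintf("< %.2g (%.0f%%)", sesoi,
                                   100 * split$prop_below),
                 `TRUE` = sprintf("≥ %.2g (%.0f%%)", sesoi,
                                  100 * split$prop_at_or_above)),
      name = NULL
    ) +
    ggplot2::geom_vline(xintercept = sesoi, linetype = "dashed",
                        colour = "grey30") +
    ggplot2::labs(x = paste("Absolute", es_label), y = "Number of effects") +
    esd_theme()
  finish_plot(p, list(
    kind = "sesoi", sesoi = sesoi, bin_width = bin_width,
    prop_below = split$prop_below,
    prop_at_or_above = split$prop_at_or_above,
    n = length(v),
    seg_left = seg$seg_left, seg_right = seg$seg_right,
    seg_count = seg$count, seg_above = seg$above
  ), path)
}

#' Iceberg plot: raw distribution above, adjusted distribution below
#'
#' Mirrored histograms of the signed effect-size distribution before (above
#' the axis, light blue) and after (below the axis, dark blue) limit-meta
#' publication-bias adjustment, with a summary-effect diamond and 95% CI for
#' each distribution. Both halves use the same zero-anchored bins.
#'
#' @inheritParams plot_esd
#' @param se Standard-error column name.
#' @return A ggplot; the manifest lists both halves' bins and counts and the
#'   two diamonds (`estimate`, `ci_low`, `ci_high`).
#' @export
plot_iceberg <- function(data, bin_width = 0.1, es_label = "Hedges' g",
                         path = NULL, es = "yi", se = "sei") {
  fit <- fit_limit_meta(data, es = es, se = se)
  raw <- fit$data$yi
  adj <- fit$shrunken
  all_idx <- floor(c(raw, adj) / bin_width + 1e-9)
  rng <- seq(min(all_idx), max(all_idx))
  count_on <- function(x) {
    as.integer(table(factor(floor(x / bin_width + 1e-9), levels = rng)))
  }
  bins <- tibble::tibble(
    bin_left = rng * bin_width,
    bin_right = (rng + 1) * bin_width,
    raw_count = count_on(raw),
    adjusted_count = count_on(adj)
  )
  top <- max(bins$raw_count)
  bottom <- max(bins$adjusted_count)
  diamonds <- tibble::tibble(
    distribution = c("raw", "adjusted"),
    estimate = c(fit$unadjusted$estimate, fit$adjusted$estimate),
    ci_low = c(fit$unadjusted$ci_low, fit$adjusted$ci_low),
    ci_high = c(fit$unadjusted$ci_high, fit$adjusted$ci_high),
    y = c(top * 0.08, -bottom * 0.08)
  )
  mid <- (bins$bin_left + bins$bin_right) / 2
  p <- ggplot2::ggplot() +
    ggplot2::geom_col(
      data = bins, ggplot2::aes(x = mid, y = .data$raw_count),
      width = bin_width, fill = "#9ecae1", colour = "white"
    ) +
    ggplot2::geom_col(
      data = bins, ggplot2::aes(x = mid, y = -.data$adjusted_count),
      width = bin_width, fill = "#08519c", colour = "white"
    ) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey20") +
    ggplot2::geom_errorbarh(
      data = diamonds,
      ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high, y = .data$y),
      height = 0, colour = "black"
    ) +
    ggplot2::geom_point(
      data = diamonds,
      ggplot2::aes(x = .data$estimate, y = .data$y),
      shape = 18, size = 4, colour = "black"
    ) +
    ggplot2::labs(x = es_label, y = "Number of effects (raw / adjusted)") +
    esd_theme()
  finish_plot(p, list(
    kind = "iceberg", bin_width = bin_width,
    bin_left = bins$bin_left, bin_right = bins$bin_right,
    raw_counts = bins$raw_count, adjusted_counts = bins$adjusted_count,
    n = length(raw),
    diamond_raw = c(estimate = fit$unadjusted$estimate,
                    ci_low = fit$unadjusted$ci_low,
                    ci_high = fit$unadjusted$ci_high),
    diamond_adjusted = c(estimate = fit$adjusted$estimate,
                         ci_low = fit$adjusted$ci_low,
                         ci_high = fit$adjusted$ci_high)
  ), path)
}

#' @exportS3Method ggplot2::autoplot
autoplot.esd_data <- function(object, ...) {
  plot_esd(object, ...)
}

#' @exportS3Method ggplot2::autoplot
autoplot.esd_benchmarks <- function(object, ...) {
  plot_esd_benchmarks(
    attr(object, "data", exact = TRUE),
    method = attr(object, "method", exact = TRUE),
    absolute = isTRUE(attr(object, "absolute", exact = TRUE)),
    weighted = isTRUE(attr(object, "weighted", exact = TRUE)),
    ...
  )
}

#' @exportS3Method ggplot2::autoplot
autoplot.limitmeta_fit <- function(object, ...) {
  plot_iceberg(object$data, ...)
}
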