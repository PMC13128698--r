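Package: esdbench
Title: Field-Specific Effect-Size Distribution Benchmarks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds field-specific effect-size benchmarks from meta-analytic
    data. Given a table of study-level effect sizes and standard errors, the
    package estimates quantile-based small/medium/large benchmarks (optionally
    inverse-variance weighted and/or on absolute effects), with percentile
    bootstrap confidence intervals and Bowley skewness diagnostics. It adjusts
    the empirical effect-size distribution for small-study effects via limit
    meta-analysis (radial-plot regression with shrunken per-study estimates),
    connects benchmarks to study planning through noncentral-t power,
    sample-size and sensitivity calculations, and draws the associated
    figures: distribution histograms, benchmark lines with CI ribbons,
    smallest-effect-size-of-interest splits, and mirrored raw-versus-adjusted
    "iceberg" plots. A simulator of selective publication with known truth
    supports recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    metafor,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
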