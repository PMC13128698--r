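# esdbench

Field-specific effect-size benchmarks from meta-analytic data.

Cohen's one-size-fits-all thresholds (*d* = 0.2 / 0.5 / 0.8) routinely
mislabel effects: what counts as "large" in one literature is unremarkable in
another, and powering a study on a generic "medium" effect can leave it badly
underpowered for the effects its field actually produces. `esdbench` builds
the alternative: an **effect-size distribution (ESD)** — the empirical
distribution of study-level standardised effects (Hedges' *g*) collected from
the meta-analyses of a field — and derives benchmarks, bias adjustments and
planning quantities from it.

For a table of effects *y&#8342;* with standard errors *s&#8342;* the package
computes:

- **Quantile benchmarks** — small/medium/large at the 25th/50th/75th
  percentiles ("quads") or 16.65th/50th/83.35th ("thirds"), optionally
  inverse-variance weighted (*w&#8342;* = 1/*s&#8342;*²) and/or on absolute
  effects, per group and overall, with percentile-bootstrap 95% CIs and
  Bowley's quartile skewness (Q₁ + Q₃ − 2Q₂)/(Q₃ − Q₁) as a robustness
  diagnostic.
- **Publication-bias adjustment** via limit meta-analysis: a
  DerSimonian–Laird random-effects fit supplies τ², the generalised radial
  plot (z&#8342; = y&#8342;/√(s&#8342;² + τ²) on x&#8342; = 1/√(s&#8342;² + τ²))
  yields a small-study-effect intercept α and limit effect β, and each study
  is shrunk toward its infinite-precision limit,
  ỹ&#8342; = β + τ(y&#8342; − β)/√(s&#8342;² + τ²), giving a bias-adjusted ESD
  and an adjusted summary effect β + τα.
- **Power and sensitivity** for paired/one-sample and two-sample *t* tests
  via the noncentral *t* distribution: power at a given (*d*, *n*), the
  smallest *n* reaching a target power, the minimal detectable *d*, and the
  proportion of the ESD a planned design can reliably detect.
- **Figures** — ESD histograms, benchmark lines with CI ribbons, SESOI
  (smallest effect size of interest) splits, and the mirrored raw-vs-adjusted
  "iceberg" plot — each carrying a machine-readable manifest of its drawn
  elements.
- **A literature simulator** with known truth (μ, τ, one-sided selection
  severity) for recovery experiments.

## Worked example

Simulate a literature of 120 published effects whose true mean is μ = 0.2
(τ = 0.1) under strong one-sided selection, then benchmark and adjust it:

```r
library(esdbench)

lit <- simulate_literature(k = 120, mu = 0.2, tau = 0.1,
                           selection = 0.8, seed = 42)
esd_table(lit, ci = TRUE, seed = 1)
#> Effect size benchmarks (quads: 25% / 50% / 75% percentiles)
#>   group small medium large n_effects small_low small_high medium_low ...
#> 1 All    0.26   0.36  0.49       120       0.2       0.31       0.34

esd_table_pba(lit, seed = 1)
#> Effect size benchmarks, raw vs. publication-bias adjusted (25% / 50% / 75% percentiles)
#>   distribution         small medium large n_effects
#> 1 Raw effect size       0.26   0.36  0.49       120
#> 2 Adjusted effect size  0.2    0.25  0.31       120
```

Selective publication has inflated the raw median to 0.36 — nearly double
the true mean. The limit-meta shrunken distribution pulls the median back to
0.25, close to the truth the simulator planted; `fit_limit_meta(lit)` shows
the machinery (α = 0.91, a strong small-study effect; adjusted summary 0.25
[0.15, 0.35] versus the naive 0.34 [0.30, 0.38]).

Planning against the same distribution:

```r
required_n(d = 0.5, power = 0.80, tails = "one", design = "paired")
#> [1] 27
power_t(d = 0.4, n = 27, tails = "one", design = "paired")
#> [1] 0.6476759
detectable_proportion(lit, n = 40, power_levels = c(0.8, 0.9),
                      tails = "one", design = "paired")
#> # A tibble: 2 × 3
#>   power detectable_d prop_detectable
#> 1   0.8        0.400           0.425
#> 2   0.9        0.471           0.283
```

A "medium" effect by the generic heuristic (*d* = 0.5) needs N = 27 pairs
for 80% one-tailed power — but if the field's median effect is 0.4, that
design only has 64.8% power, and at N = 40 it reliably detects just 42% of
the effects this literature reports.

Plots work the same way (`plot_esd()`, `plot_esd_benchmarks()`,
`plot_sesoi()`, `plot_iceberg()`, or `autoplot()` on fitted objects); every
plot's content is inspectable via `plot_manifest()`.

A command-line interface wraps the same functions:

```sh
Rscript inst/scripts/esdist.R benchmarks --input effects.csv --ci --seed 1
Rscript inst/scripts/esdist.R power --d 0.5 --power 0.8 --tails one --design paired
```

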