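---
title: "Effect-size distribution benchmarks: models, conventions and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Effect-size distribution benchmarks: models, conventions and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(esdbench)
```

## The problem

Interpreting an observed standardised effect ("is *g* = 0.35 small or
large?") and planning a study ("what effect should my power analysis
assume?") both need a reference distribution. Generic heuristics ignore that
fields differ enormously in their typical effects. `esdbench` takes the
empirical route: collect the study-level effects a field has actually
reported — one per study, in a common metric — and treat quantiles of that
**effect-size distribution (ESD)** as the field's own benchmarks.

This vignette records the modelling choices, conventions and their
rationale, and what the package's tests do and do not establish.

## Data model and filtering

The substrate is a flat table: one row per effect with estimate `yi` and
standard error `sei` (Hedges' *g* by default), plus optional `study_id`,
`group` and `n_total` columns. Validation is strict — non-finite effects,
non-positive SEs or `n_total < 2` are errors naming the offending rows;
silently dropping rows is opt-in (`skip_invalid`) and always counted in the
attached report.

When a study contributes several effects, keeping all of them would let
multi-outcome studies dominate the ESD. `dedupe_by_study()` keeps exactly
one effect per study: the one with the smallest standard error; ties on the
SE are broken by the effect closest to zero regardless of sign (a
conservative choice — when precision cannot discriminate, prefer the weaker
claim); a remaining exact tie keeps the first in input order, making the
operation deterministic and idempotent.

Conversions to the common metric use the standard small-sample correction
`g = d * (1 - 3/(4 df - 1))` (with `df = n1 + n2 - 2` for two-sample and
`n - 1` for paired designs); the exact gamma-function correction differs
only in the fourth decimal for the sample sizes that occur in practice.
Correlation inputs convert via `d = 2 r / sqrt(1 - r^2)` as an explicit
opt-in, because the appropriate conversion depends on the design behind the
correlation.

## Quantile conventions

Benchmarks are quantiles: 25/50/75% ("quads") or 16.65/50/83.35%
("thirds" — the printed convention for equal thirds, kept as printed rather
than 1/6 and 5/6). Two conventions needed fixing:

**Unweighted.** Linear interpolation between order statistics at index
`h = p (n - 1)` — the default of essentially every statistical environment
(type 7). Nothing in the method depends delicately on this choice, but
fixing it makes tables reproducible to the digit.

**Inverse-variance weighted.** With weights `w_i = 1/sei^2`, sorted values
get midpoint cumulative weights `c_k = (sum_{j<=k} w_j - w_k/2) / sum(w)`,
and the estimate interpolates the sorted values at
`t = c_1 + p (c_n - c_1)`. Mapping `p` affinely onto `[c_1, c_n]` (rather
than using `p` directly) is what makes equal weights reproduce the
unweighted type-7 estimator *exactly* — a property the test suite asserts on
randomised instances, and the natural compatibility requirement for a
weighted generalisation. For integer-ratio weights the estimator agrees with
the brute-force "replicate each value w times" oracle wherever the quantile
is uniquely defined (the cumulative crossing falls inside a run of one
value); inside interpolation bands the two differ by construction, bounded
by neighbouring order statistics, which the property tests check.

**Bowley skewness** `(Q1 + Q3 - 2 Q2)/(Q3 - Q1)` uses the same quantile
engine, is bounded in [-1, 1], and is reported as a robustness diagnostic:
a strongly right-skewed ESD is a warning sign (e.g. of small-study effects)
that the benchmarks lean on a heavy upper tail. It is undefined when
Q1 = Q3 (reported as an error, or NA inside tables).

Group tables omit groups with fewer than `min_group_n` effects. The default
is 3 — the most permissive defensible threshold, since any 3 points define
the quartiles only through heavy interpolation already — and it is an
explicit parameter because sensible practice varies (the worked analyses
this package emulates use 3 in text and 4 in tables).

## Bootstrap confidence intervals

Benchmark CIs are percentile bootstrap: resample *n* effects with
replacement, recompute the quantile, take the 2.5th/97.5th percentiles of
`n_boot = 2000` replicates (per group, for grouped tables). A seed is
*required* whenever CIs are requested — reproducibility is not optional —
and all randomness flows through `withr::with_seed`, leaving the caller's
RNG state untouched. In the weighted case resampling probabilities are
proportional to the weights and the replicate quantile is unweighted: the
weights are consumed by the resampling step, which keeps the replicate
distribution a genuine resample of the weighted estimand.

Percentile-bootstrap intervals for quantiles are known to be slightly
anti-conservative at extreme quantiles and small *n*; the suite verifies
coverage empirically for the median of normal samples (n = 200, 1000
simulations, `n_boot` = 1000 — sizes chosen to estimate a coverage
proportion to about ±1.5 points), requiring the 93–97% band around the
nominal 95%.

## Limit meta-analysis and the adjusted ESD

Publication bias — significant results being likelier to be published —
inflates naive summaries, and small-study effects are its classic
signature. The adjustment pipeline:

1. **Random effects.** DerSimonian–Laird, chosen for its closed form: every
   number it produces can be re-derived by hand, which the tests exploit
   (naive-formula oracle at 1e-10 and agreement with `metafor::rma`,
   `method = "DL"`). REML/ML variants would change τ² in the third decimal
   for realistic data; determinism and transparency won.
2. **Radial regression.** OLS of `z_i = y_i/sqrt(s_i^2 + tau^2)` on
   `x_i = 1/sqrt(s_i^2 + tau^2)` gives intercept α (small-study effect) and
   slope β (the limit effect: what an infinitely precise study would show).
   The radial construction standardises residuals to unit variance, so the
   coefficient covariance uses σ² = 1 rather than the estimated residual
   variance. The regression is refused (as unidentifiable) when all `x_i`
   agree within 1e-10 — equal SEs carry no small-study information.
3. **Shrinkage.** `y~_i = beta + tau (y_i - beta)/sqrt(s_i^2 + tau^2)`.
   Each effect moves toward β by a factor `tau/sqrt(s_i^2+tau^2)` in [0, 1]:
   imprecise studies shrink almost completely, precise ones barely move. At
   τ = 0 the distribution collapses to β; as τ → ∞ the data are returned
   unchanged. Note the factor is per-study, so the *global* ranking of
   effects is not preserved across different SEs — only the sign and
   magnitude of each study's displacement from β are.
4. **Adjusted summary.** β + τα, the expectation of the extended model, with
   a delta-method CI treating τ as fixed. Published variants differ (some
   report β alone, some a μ-limit); the expectation variant is reported
   because it is the mean of the adjusted distribution the package actually
   produces, so table and plot agree internally.

Paired raw/adjusted benchmark tables always shrink the *signed* effects
first and fold to absolute values afterwards (when requested): magnitudes
taken before adjustment would double-count the bias being removed.

## Power and sensitivity

All power calculations use the noncentral *t* distribution exactly
(`pt(..., ncp)`), not the normal approximation: paired/one-sample designs
have `df = n - 1`, `ncp = d sqrt(n)`; equal-*n* two-sample designs
`df = 2n - 2`, `ncp = d sqrt(n/2)`. α defaults to 0.05. Two-tailed power
includes the far-tail rejection region — numerically negligible but
definitionally correct (base R's `power.t.test` drops it, and the tests
account for exactly that term when cross-checking). Sample-size search is
integer bisection after bracketing by doubling, so the returned *n* is the
*smallest* integer meeting the target; minimal detectable effects come from
root finding on *d* in (1e-6, 10] to 1e-6. `detectable_proportion()` chains
the sensitivity solution with the SESOI split to report how much of an ESD
a design can reach at each power level.

## The literature simulator

`simulate_literature()` is the package's test bed and defines the
conditions under which the recovery claims are verified. Per candidate
study: per-group sample size *n* uniform on `n_range` (default 10–100, a
typical small-experiment range); true effect θ ~ N(μ, τ²); sampling SE from
the large-sample variance of a two-sample standardised mean difference with
equal arms, `se = sqrt(2/n + theta^2/(4 n))`; observed `y ~ N(theta, se^2)`.
Selection is a two-point mechanism on the one-sided *p* from `z = y/se`:
*p* < 0.05 always publishes, otherwise publication has probability
`1 - selection`. Defaults μ = 0.2, τ = 0.1 — a small true effect with
moderate heterogeneity, the regime where publication bias does the most
interpretive damage and the configuration used throughout the recovery
tests (k = 50 published effects, selection 0.9, 200 replicates).

What the simulator does **not** emulate: correlated multi-effect studies,
metric heterogeneity and conversion error, richer selection curves
(gradual *p*-dependence, sign flips), rounding of reported statistics, or
time trends. Passing recovery tests therefore show that the adjustment
removes the bias *this* mechanism induces — they do not certify performance
on any particular real literature, where the selection process is unknown.

## Figures

Histograms use half-open bins `[a, a + w)` anchored at zero (default width
0.1 *g*-units), with a small relative tolerance so decimal values on bin
edges land in the upper bin despite floating-point representation. Every
plot function returns a ggplot whose drawn content — bin edges, counts,
benchmark line positions, CI bands, SESOI proportions, diamond coordinates —
is attached as a manifest (`plot_manifest()`), so the suite asserts figure
content without pixel comparison and CLI runs can emit the manifest as a
JSON side-file. The benchmark figure plots the absolute distribution by
default (its caption-style annotation rounds to 2 decimals); the plain ESD
histogram is signed; the iceberg plot mirrors the adjusted distribution
below the axis with a summary diamond per half.

## Problem sizes and determinism

The default test run keeps every stochastic check seeded and sized to
finish in minutes: 1000-instance property sweeps for the quantile engine,
200-instance oracle comparisons for the meta-analytic fits, 1000×1000
bootstrap coverage, and a 200-replicate recovery experiment. Sizes are
stated next to each test; all are the package's own choices balancing
Monte-Carlo error against runtime, and every one runs from a fixed seed so
failures are reproducible, never flaky.

## Known limitations

- Benchmarks inherit every bias of the underlying meta-analytic corpus;
  the limit-meta adjustment addresses small-study effects specifically, not
  selective outcome reporting or p-hacking within studies.
- The DL/OLS pipeline is deliberately simple; joint likelihood fits of the
  extended random-effects model are out of scope, and exact reproduction of
  third-party adjusted tables can differ in the second decimal with the τ²
  estimator.
- Weighted bootstrap CIs use weighted *resampling* with unweighted replicate
  quantiles; other weighted-bootstrap schemes exist.
- Power utilities cover *t*-test designs only (paired/one-sample and
  equal-*n* two-sample).
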