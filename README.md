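# bmibias

Quantile-matching correction of self-report bias in survey BMI, with
design-weighted prevalence estimation of severe obesity.

## The problem

Large surveillance surveys (such as state-based telephone surveys) collect
*self-reported* height and weight. People tend to under-report weight and
over-report height, and the distortion grows with BMI, so prevalence of
severe (class III) obesity — BMI ≥ 40 kg/m² — computed from self-reports is
badly underestimated. Examination surveys measure height and weight
directly, but are far too small for state-level estimates. `bmibias`
implements the distribution-matching correction that combines the two: it
adjusts the whole self-reported BMI distribution to agree with a measured
reference, which recovers the distribution's right tail far better than
regression-style corrections.

## The method

Within each sex × age-group stratum (18–34, 35–49, 50–64, ≥65):

1. Estimate the quantile-specific bias between a self-reported reference
   survey and a measured reference survey over an equally spaced probability
   grid (default 99 percentiles),

   δ(p) = Q_measured(p) − Q_self-reported(p),

   where Q(·) is the sample-weighted quantile function (weighted-ECDF
   inverse with linear interpolation at cumulative-weight midpoints).
2. Fit a cubic spline to (p, δ(p)) — by default a natural interpolating
   spline, optionally a GCV smoothing spline — clamped to its endpoint
   values outside the grid.
3. For each participant of the target survey, compute the sample-weighted
   quantile rank p_i of their self-reported BMI within their own stratum and
   correct additively:

   BMI_corrected,i = BMI_i + δ(p_i).

4. Validate with a weighted two-sample Kolmogorov–Smirnov test (effective
   sample sizes n_eff = (Σw)²/Σw²) that the corrected and measured
   distributions are statistically indistinguishable (p > .05).

Prevalence of severe obesity is then the Hájek estimator
p̂ = Σwᵢxᵢ/Σwᵢ with weights-only linearized standard errors and
logit-transformed 95% CIs; subgroup and state-versus-national contrasts use
large-sample z tests.

Because real reference and target microdata are restricted, the package
ships a synthetic paired-survey generator with known ground truth (measured
BMI mixtures per stratum, a parametric reporting-bias mechanism, log-normal
sampling weights, and exclusion-triggering records), so every stage is
testable end to end, plus delimited-text transcriptions of published
subgroup and state prevalence tables for the reporting layer.

## Worked example

```r
library(bmibias)

cfg <- run_config(population = population_config(n = 50000), seed = 2026)
m <- run_pipeline(cfg)

cat(sprintf("true severe-obesity prevalence (generator): %.2f%%\n", m$truth_pct))
cat(sprintf("self-reported estimate:                     %.2f%%\n", m$self_reported_pct))
cat(sprintf("bias-corrected estimate:                    %.2f%%\n", m$corrected_pct))
cat(sprintf("post-correction KS: D = %.4f, p = %.2f\n",
            m$ks$statistic, m$ks$p_value))
```

```
true severe-obesity prevalence (generator): 8.78%
self-reported estimate:                     5.06%
bias-corrected estimate:                    8.36%
post-correction KS: D = 0.0077, p = 0.47
```

The naive self-reported estimate misses about 40% of the true prevalence;
the corrected estimate recovers it to within sampling error, and the
corrected distribution is statistically indistinguishable from the measured
reference. The same reporting functions run on the packaged published-table
fixtures:

```r
tab2 <- load_prevalence_table(bmibias_fixture("table2_severe_obesity_states.tsv"))
column_extremes(tab2, "corrected_total")
#> state corrected range: 5.5% (Massachusetts) to 13.2% (West Virginia)
count_above(tab2, "corrected_total", 10)
#> [1] 16
```

A declarative YAML config plus a thin command-line wrapper
(`inst/scripts/run-pipeline.R`) run the same pipeline from a shell; see
`?read_run_config`.

## Package layout

- `R/` — synthetic-data generator, cohort exclusion filters, weighted
  quantile/rank engine, bias-curve estimation and correction, weighted KS
  test, survey estimation, reporting, pipeline orchestration.
- `inst/extdata/` — published-style prevalence-table fixtures (TSV).
- `vignettes/bmi-bias-correction.Rmd` — the methods vignette: model,
  assumptions, defaults, numerical choices, limitations.
- `tests/testthat/` — unit, property and acceptance suites with
  independent oracles (replication-expansion quantiles, numerical mixture
  integration, brute-force ECDF sweeps, classical KS cross-checks).
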