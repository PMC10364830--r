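---
title: "Correcting self-report bias in survey BMI by quantile matching"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correcting self-report bias in survey BMI by quantile matching}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bmibias)
```

## The measurement problem

Self-reported height and weight understate BMI: respondents under-report
weight and over-report height, and both distortions worsen at higher BMI.
A prevalence defined by a right-tail threshold — severe (class III) obesity,
BMI ≥ 40 kg/m² — is therefore severely underestimated from self-reports.
Regression-style corrections that predict measured BMI from reported BMI
shrink toward the mean and still miss the tail. Distribution matching avoids
this: if a self-reported survey and a measured survey describe the same
population, then whatever mass the measured distribution has at its p-th
quantile, the corrected self-reported distribution should have too.

`bmibias` works on the BMI scale directly rather than correcting height and
weight separately, which keeps each record's height/weight/BMI triple
internally consistent (reported weight is back-solved at unchanged height
wherever BMI changes).

## The correction model

All estimation is stratified by sex × age group (18–34, 35–49, 50–64, ≥65);
eight strata in total. Within a stratum, with `Q_m` and `Q_s` the
sample-weighted quantile functions of the measured and self-reported
reference surveys:

$$\delta(p) = Q_m(p) - Q_s(p), \qquad p \in \{ \tfrac{1}{K+1}, \dots, \tfrac{K}{K+1} \},$$

with `K = 99` grid points by default (the 1st–99th percentiles). A cubic
spline is fitted to $(p, \delta(p))$ and each target-survey participant is
corrected additively at their own weighted quantile rank, computed within
their stratum *of the target survey*:

$$\mathrm{BMI}^{corr}_i = \mathrm{BMI}_i + \delta_s\!\big(\mathrm{rank}_s(\mathrm{BMI}_i)\big).$$

The sign convention makes zero bias the identity: $\delta > 0$ means
self-reports understate BMI and the correction adds it back.

### Weighted quantiles and ranks

The quantile engine inverts the weighted ECDF with linear interpolation
between distinct order statistics placed at normalized cumulative-weight
midpoints $(c_i - w_i/2)/W$ (ties pool their weight and share the pooled
midpoint). With unit weights this is the Hazen plotting-position convention
(`stats::quantile` type 5), and for integer weights it coincides with
replicating each observation `w` times and taking the empirical quantile of
the expanded list — the invariance the test suite checks against an
enumeration oracle. `weighted_rank()` is the exact inverse on the
interpolation range, so rank-then-evaluate round-trips to the identity;
`p = 0`/`p = 1` return the sample extremes and out-of-range values rank 0
or 1.

### Spline choice

The default is a **natural interpolating cubic spline** through the raw
quantile differences. Neighbouring empirical quantiles share most of their
data, so $\delta(p)$ is already a smooth function of $p$ at reference sizes
in the tens of thousands; interpolation preserves the quantile-matching
property essentially exactly (correcting the self-reported reference
against its own curves reproduces the measured reference's grid quantiles
to within 0.1 BMI units — the package's stated spline tolerance, verified
at survey scale in the acceptance suite). A generalized-cross-validated
smoothing spline (`spline = "smooth"`, optional `spar`) is available for
small or noisy references; it buys noise suppression at the cost of bias at
the extreme grid percentiles, where we measured deviations up to ~0.4 BMI
units, so it is not the default.

Outside the grid the curve is **clamped** to its endpoint values: beyond the
1st and 99th percentiles quantile differences are unidentified and
polynomial extrapolation would manufacture wild tail corrections.

### Monotonicity

Nothing forces $v \mapsto v + \delta(\mathrm{rank}(v))$ to be monotone. The
package counts adjacent-rank order inversions after correction and reports
them in the `n_inversions` attribute and the pipeline manifest; an optional
weighted-isotonic post-adjustment (`isotonic = TRUE`) restores monotonicity.
It is off by default: the inversions are local reshuffling at the scale of
the reporting noise, they do not move distribution-level estimates, and a
visible diagnostic is preferable to silent reordering.

### Validation

`ks_compare()` computes $D = \sup_t |F_a(t) - F_b(t)|$ over the pooled
support of the two weighted ECDFs and refers $\sqrt{n}\,D$ (with
$n = n_{eff,a} n_{eff,b} / (n_{eff,a} + n_{eff,b})$,
$n_{eff} = (\sum w)^2/\sum w^2$) to the asymptotic Kolmogorov distribution.
With unit weights the statistic equals the classical two-sample statistic
exactly; p-values agree with `stats::ks.test(exact = FALSE)` to ~1e-4
because our Kolmogorov series is summed to convergence while the reference
implementation truncates its theta series. The pipeline runs the test both
pooled and per stratum and reports both, since a pooled comparison can mask
compensating stratum-level differences.

## Survey estimation

Prevalence is the Hájek ratio $\hat p = \sum w_i x_i / \sum w_i$ with the
weights-only linearization $se^2 = \sum w_i^2 (x_i - \hat p)^2 / (\sum w_i)^2$.
Without strata/PSU identifiers a full design-based variance (as produced by
survey software on the real microdata) is not computable; the weights-only
linearization is the best available approximation and is what the CI
calibration test exercises (93–97% empirical coverage on weighted Bernoulli
draws, 1,000 replicates of n = 2,000, weight CV ≈ 1). Confidence intervals
are built on the logit scale and mapped back, keeping bounds inside [0, 1]
for small prevalences; degenerate estimates (0 or 1) get exact one-sided
bounds at the effective sample size. Subgroup contrasts are large-sample
two-sided z tests with no multiplicity adjustment. Severe obesity is
classified boundary-inclusively, BMI ≥ 40.

### Re-testing published tables

Published tables print estimates and 95% CIs but not standard errors;
`se_from_ci()` recovers `se = (ci_high − ci_low)/(2 × 1.96)`.
`flag_above_national()` re-tests each state row against the national
estimate with SEs recovered this way. Because the scientific question is
directional — *which states sit above the national average?* — the default
is a one-sided test at α = .05, which reproduces the footnote markers of
the packaged state table exactly. A two-sided variant is provided; on CIs
rounded to one decimal it loses the two borderline states (one-sided
p just under .05, two-sided just over), a divergence the test suite
documents explicitly. State counts exclude the District of Columbia
by default (`include_dc`), matching "n states" phrasing while keeping DC in
the table.

## The synthetic study design

`make_paired_surveys()` draws three independent surveys from one generating
process: a measured reference, a self-reported reference over the same
period (these two identify the bias curves), and an independent
self-reported target to be corrected — the same roles the real
examination/telephone surveys play.

**Measured BMI** per stratum is a two-component log-normal mixture (bulk +
heavy right tail). The defaults were set once so that the analytic
severe-obesity tail mass is ≈ 8.8% overall, ≈ 11% among women and ≈ 6.5%
among men with a hump-shaped age profile — the magnitude and ordering seen
in measured US adult data. `severe_obesity_truth()` returns the closed-form
tail mass, which is the ground truth the corrected estimates must recover;
an independent numerical-integration oracle confirms it in the tests.

**Reporting bias** is an explicit parametric mechanism on the BMI scale:
reported = measured − (intercept + slope·max(0, measured − pivot) +
sex offset + age offset) + Normal(0, noise_sd), defaults intercept 0.4,
slope 0.18 above a pivot of 25, offsets making women and younger adults
under-report more, noise SD 0.5 (all in kg/m²). The empirical bias in real
survey pairs is not a generative model; this piecewise-linear form is the
simplest mechanism that reproduces its two robust qualitative features —
reported BMI is biased down, and more so at higher BMI — while remaining
analytically checkable (slope < 1 keeps reporting monotone in measured
BMI). Under these defaults the naive self-reported severe-obesity
prevalence runs ≈ 40% relatively below truth, matching the distortion scale
the method is designed to remove.

**Sampling weights** are log-normal, normalized to mean 1, with coefficient
of variation `weight_dispersion` (default 1; zero gives equal weights).
**Exclusion-triggering records** — pregnancy flags (women under 50, rate
0.005), missing demographics and anthropometrics (rates 0.2–1%), and
biologically implausible heights/weights (rate 0.002) — are injected
completely at random, which is sufficient to exercise the filter module
without biasing downstream estimates.

What the generator does *not* emulate: telephone-survey design features
(strata, PSUs, raking), informative missingness, pregnancy or
race/ethnicity effects on BMI, and secular drift between the reference
period and the target year. Passing tests therefore demonstrate that the
implementation recovers known truth under the assumed mechanism — not that
the bias curves of any particular real survey pair look like these.

## Cohort filters

Exclusions run sequentially — pregnant → missing sex → missing age →
missing race/ethnicity → missing or implausible anthropometrics — with each
record counted at the first criterion it fails, so the log telescopes and
the final count is the analytic sample. Implausibility bounds are height
below 50 cm or above 300 cm, or weight below 20 kg, read as a list of
conditions any one of which excludes; the stated boundary values themselves
are plausible and kept. Missing pregnancy status is treated as not
pregnant. The retained set is identical under any criterion ordering; only
attribution moves.

## Numerical and scale choices

- Grid: 99 equally spaced interior probabilities; `grid_size` configurable
  (minimum 4).
- Ties in values use the pooled-midpoint convention everywhere —
  deterministic and symmetric under reordering.
- Stage seeds are derived deterministically from one run seed; identical
  config + seed give identical manifests, byte for byte.
- Test problem sizes: parameter recovery uses three surveys of n = 100,000
  over 5 seeds (corrected estimate within ±0.5 percentage points of the
  analytic truth while the naive estimate is ≥ 20% relatively below);
  quantile-matching exactness n = 50,000; KS validation 20 replicates at
  n = 20,000 (p > .05 required in ≥ 90%); CI calibration 1,000 replicates
  at n = 2,000. These sizes put Monte Carlo error well inside each
  tolerance while a full run stays interactive on a laptop.

## Limitations

- Variance estimation is weights-only; against genuinely clustered designs
  it understates design effects beyond unequal weighting.
- The reference pair is treated as one period; real applications pool
  several reference years and cannot see distribution shifts within the
  pooled window.
- Bias curves are fitted independently per stratum; no smoothing is shared
  across strata, so very sparse strata need either pooling or the smoothing
  spline.
- The correction is exchangeable at equal quantile ranks: it matches
  distributions, not individuals, and corrected individual BMIs are only
  meaningful in aggregate.
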