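---
title: "Prognostic validity of a multifactorial fall risk score: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prognostic validity of a multifactorial fall risk score: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fallrisk)
```

## The question and the data model

Multifactorial fall-risk assessment summarises a resident's intrinsic and
extrinsic risk factors into a single Fall Risk Score (FRS) on a 0–100
scale. This package asks the prognostic question: does the score measured
at a baseline assessment (T1) predict how often the resident falls before
the follow-up assessment (T2)?

The unit of analysis is the *observation pair*: two consecutive
assessments of the same resident separated by 45–180 days. Residents
contribute as many pairs as they have consecutive eligible assessments;
non-consecutive combinations are never formed, which keeps each reported
fall attached to exactly one observation window (fall counts are conserved
across pairing, a property the test suite checks). Reported falls are
normalized by the window length and analysed as falls per week
(`7 × falls / interval days`), since windows vary three-fold in length.

## Scoring

`compute_frs()` scores a profile as the weighted percentage of catalog
factors present. The anchors define the normalization: an empty profile
scores 0, a complete profile scores 100, so the score is the weighted sum
divided by the maximum attainable weighted sum. The default catalog holds
nine double-weighted and six single-weighted factors (total weight 24);
the catalog is data, not code — any `data.frame` of positive weights, or a
JSON document read with `read_weight_config()`, can replace it. Unknown
(`NA`) flags are conservatively treated as absent, with a warning, because
an unanswered questionnaire item is evidence of nothing. Gait-derived
information enters through `flag_limited_mobility()`: gait speed below 0.6
m/s — the same cut used by the subgroup analysis — flags the
limited-mobility factor by default.

## Smoothing, fitting, selection

Raw weekly rates are mostly zeros with occasional positive values, so the
association with FRS is estimated on a running average: for every distinct
integer FRS value observed at T1, the mean weekly rate over all pairs
within ±1 FRS point (a window of 2 points on the 0–100 scale). The window
is read as a *fixed* width of 2 percentage points, centred; an adaptive
variant (width proportional to the local FRS value, `adaptive = TRUE`) is
provided for comparison but degenerates to zero width near FRS 0 and is
not the default. Because neighbouring windows share observations, the
smoothed points are autocorrelated; p-values computed on them are
descriptive, not strictly nominal, and are labelled as such here.

Three families are fitted to the smoothed points in ascending order of
complexity: linear and quadratic by ordinary least squares, and
`a·exp(b·FRS) + c` by Levenberg–Marquardt nonlinear least squares
(initialised at `a = range of rates`, `b = 0.01`, `c = minimum rate`,
200 iterations; a constant curve is fitted exactly by the degenerate
`a = 0` solution instead of iterating). A nonlinear fit that fails is
returned flagged as non-converged rather than dropped. Selection is by
lowest RMSE against the smoothed points — training RMSE, deliberately, as
no out-of-sample claim is made; since the linear model is nested in the
quadratic, RMSE(quadratic) ≤ RMSE(linear) always, and exact RMSE ties are
broken toward the fewer-parameter family, then toward the declared order
linear < quadratic < exponential.

## Thresholds

The selected quadratic maps a score to an expected weekly fall rate;
multiplying by a horizon of 26, 52 or 104 weeks and solving
`rate(FRS) × horizon = 1` for the positive root gives the score at which
one fall is expected within 6, 12 or 24 months. The root is rounded *up*
to the next integer percent — the threshold is the smallest score at which
the expectation is reached ("starting at"), and round-up is the reading
that reproduces the published values 45/32/24 from the published
coefficients. If the expectation never reaches 1 on [0, 100] a flagged
no-threshold result is returned.

## MCID

The minimal clinically important difference is distribution-based:
`effect size × pooled SD`, with the conventional anchors 0.2/0.5/0.8. The
pooled SD is the symmetric form `√((SD²_T1 + SD²_T2)/2)`, under which two
equal SDs pool to themselves; with baseline and follow-up SDs of 11.8 and
11.5 points this yields 11.65 and MCIDs of 2.3/5.8/9.3 at one decimal.
Confidence intervals come from a percentile bootstrap (default 10,000
replicates) that resamples observation rows with T1/T2 kept paired;
`cluster =` switches to resampling whole residents, for readers who prefer
to treat repeated observations of one person as one resampling unit.
Estimates are reported at full precision and rounded to one decimal only
in `mcid_table()`.

## Subgroups

`subgroup_pipeline()` repeats smoothing, fitting, selection and the
Spearman analysis inside each stratum of eight schemes: interval binned to
the nearest of 60/90/120 days (ties round down, so 75 days goes to 60),
disease count (0/1/2/3/≥4 over the 15-disease list, carried as a count
column), age (<65, 65–74, 75–85, >85 — implemented as [65,75), [75,85],
(85,∞) because the natural-language bands overlap at their boundaries),
gait speed (boundary 0.6 m/s assigned to the closed upper bin ≥0.6),
dementia, the two gait/dementia extremes, fall history and walking-aid
use. Pairs with a missing covariate are routed to an explicit unassigned
set, never silently dropped, and each scheme's strata partition the
assigned pairs (a tested invariant). Strata whose smoothed curve has
fewer than 10 points (configurable) are reported as "insufficient" with
no fit attempted. No multiplicity correction is applied across strata.

## The synthetic generator

`generate_cohort()` exists so that every stage can be exercised, at any
scale, without resident data. Its defaults are fixed to the reference
study population and are not tuning knobs:

* baseline FRS truncated-normal, mean 29.7, SD 11.8, range [1, 71];
* follow-up FRS via a bivariate-normal step with marginal mean 29.2 and
  SD 11.5 and correlation 0.9 with baseline (the paper-style descriptives
  fix the marginals; the correlation is this package's assumption about
  test–retest stability of a multifactorial score over ~3 months);
* intervals truncated-normal, mean 108.5, SD 31.6 days, range [45, 180];
* fall counts Poisson with mean `max(0, rate(FRS_T1)) × interval/7`,
  where `rate` is the published quadratic (`reference_fall_model()`). The
  clamp at zero is required because the quadratic is negative below
  FRS ≈ 10 and a Poisson mean cannot be; a negative-binomial
  `overdispersion` size parameter is available since real fall counts
  (weekly mean 0.02, SD 0.05) look overdispersed;
* covariates at the study prevalences (walking aids 622/857, dementia
  277/857, fall history 125/857, women 615/857, age 83.3 ± 8.7 truncated
  at 60, gait speed 0.49 ± 0.19, disease count Poisson(2.1)). Covariates
  are independent except that walking-aid use is coupled to gait speed
  below 0.6 m/s, keeping the marginal prevalence near its target; the
  externally-assessed mode coincides with dementia, mirroring the
  reference descriptives in which the two counts coincide.

All scores live on the configured truncated scale [1, 71]: every
generated assessment can serve as the baseline of the next observation
pair, so letting follow-up scores wander above the baseline range would
create observations outside the stated score distribution (the reference
data's follow-up maximum of 77 is a feature the generator deliberately
does not reproduce). Truncation also means the *sample* mean of the
generated scores sits slightly above the 29.7 location parameter
(analytically ≈ 29.94); the tests check moments against the analytic
truncated-normal values, not the location parameters.

What passing tests on this generator do **not** show: real cohorts have
informative missingness, correlated covariates beyond the one coupling
modelled here, reporting error in recalled falls, and feedback between
falling and subsequent scores — none of which the generator emulates.

## Numerical choices and known limits

* Sample SDs use the n−1 denominator throughout; α = 0.05 is recorded in
  the run manifest; JSON/returned objects carry full precision and
  rounding happens only in report tables.
* Deterministic reproducibility is a contract: a fixed seed fixes the
  cohort, the bootstrap and therefore every analytical output
  (`run_full_analysis()` records seed, parameters and decision flags in
  its manifest).
* Problem sizes: the test suite runs the pipeline at cohort sizes from a
  few hundred pairs (study scale) up to ~50,000 pairs for
  parameter-recovery properties, and uses 10,000–20,000 bootstrap
  replicates; these sizes were chosen to make the stochastic properties
  sharp at desk scale.
* **Identifiability of the small coefficients.** Refitting the quadratic
  on data generated from it recovers the leading coefficient `a`, the
  rank correlation (ρ ≥ 0.9) and the inverted thresholds (within ±2 FRS
  points) robustly at 50,000 observations. The linear coefficient
  `b ≈ 3.1×10⁻⁵` and intercept `c ≈ −2.3×10⁻³` are, however, not
  identifiable to within 10% at any realistic cohort size: `b` is
  smaller than its own sampling error, and the zero-clamp on the rate
  (mandatory for a count model) biases the refitted intercept
  deterministically. The acceptance suite asserts the full
  coefficient-recovery property regardless and documents the failure,
  rather than weakening the check; users of the fitted equation should
  treat `a` and the curve's predictions as meaningful, and `b`, `c`
  individually as fit artefacts.
* At study scale (~850 pairs) the fitted leading coefficient occasionally
  comes out ≤ 0; `run_full_analysis()` then skips threshold inversion
  (which requires a convex rate curve) instead of reporting a spurious
  root.
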