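# fallrisk

Prognostic-validity analysis for a multifactorial Fall Risk Score (FRS) in
longitudinal cohorts of older adults.

Falls are a leading cause of injury and loss of independence in people aged
60 and over, and care guidelines favour multifactorial risk assessment over
single functional tests. The FRS summarises such an assessment as the
weighted percentage of fall-risk factors present, on a 0–100 scale: nine
high-impact factors (limited mobility, dizziness, visual and auditory
impairments, medication use, cognitive impairment, depression, urge
incontinence, fall history, restlessness) carry double weight, six further
factors (mobility-limiting comorbidities, foot disorders, syncope-causing
conditions, fear of falling, walking aids, environmental hazards) carry
single weight, so

```
FRS = 100 × Σᵢ wᵢ·xᵢ / Σᵢ wᵢ,   xᵢ ∈ {0, 1},  wᵢ ∈ {1, 2}.
```

This package implements the full pipeline for asking whether the FRS at a
baseline assessment (T1) predicts how often a person falls before the
follow-up assessment (T2), 45–180 days later:

1. **Cohort handling** — eligibility filtering (age ≥ 60, repeat
   assessments, compatible app versions), consecutive (T1, T2) pairing,
   and normalization of reported falls to a weekly rate
   (`7 × falls / interval days`).
2. **Prognostic curve** — a running average of the weekly fall rate over
   the FRS axis (window of 2 FRS points), ordinary-least-squares linear and
   quadratic fits plus a nonlinear exponential fit, selection by lowest
   RMSE, and Spearman rank correlation on the smoothed curve.
3. **Thresholds** — inversion of the quadratic rate model
   `rate(FRS) = a·FRS² + b·FRS + c` at `rate × horizon = 1` to find the
   smallest integer FRS at which one fall is expected within 26, 52 or 104
   weeks.
4. **MCID** — distribution-based minimal clinically important differences,
   `effect size × √((SD²_T1 + SD²_T2)/2)` for effect sizes 0.2/0.5/0.8,
   with percentile bootstrap confidence intervals.
5. **Subgroups** — the same curve analysis per interval bin, disease
   count, age band, gait speed, dementia status, fall history and
   walking-aid use.
6. **Synthetic cohorts** — a seeded generator whose defaults emulate the
   reference study population (FRS ~ truncated normal 29.7 ± 11.8 on
   [1, 71], intervals 108.5 ± 31.6 days on [45, 180], Poisson fall counts
   driven by the published quadratic rate model), so every stage is
   testable without any real resident data.

## Worked example

```r
library(fallrisk)

cohort <- generate_cohort(cohort_config(), seed = 42)  # ~850 observations
report <- run_full_analysis(cohort, replicates = 10000, seed = 42)
report
#> <frs_report> status: ok
#>   observations: 844 (excluded records: 0)
#>   selected model: quadratic (RMSE 0.01627)
#>   Spearman rho on smoothed curve: 0.822 (p = 1.48e-16)
#>   MCID (effect size -> points): 0.2 -> 2.3, 0.5 -> 5.9, 0.8 -> 9.4

mcid_table(report$mcid)
#>   effect_size  label mcid      ci
#> 1         0.2  small  2.3 2.2-2.4
#> 2         0.5 medium  5.9 5.6-6.1
#> 3         0.8  large  9.4 9.0-9.8
```

The quadratic wins model selection and the smoothed curve rises
monotonically with the baseline score (rho 0.82): residents with higher
FRS at T1 fell more often before T2. The MCID rows say that a change of
about 2.3 FRS points is the smallest shift one should treat as more than
noise, and a drop of 9 points or more after an intervention is a large
effect. At this cohort size the fitted leading coefficient can come out
slightly negative (as it does here), in which case the report skips
threshold inversion; thresholds from the published rate model are always
available directly:

```r
threshold_frs(reference_fall_model(), c(26, 52, 104))
#>  26  52 104
#>  45  32  24
```

An FRS of 45 marks the score at which one fall is expected within 6
months; 32 and 24 mark the 12- and 24-month horizons.

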