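# pxamode

Estimation of survey **mode effects** on patient experience scores from
a two-arm randomized experiment (telephone vs mobile web), with
nonresponse handled by inverse probability weighting (IPW) and multiple
imputation (MI) under the missing-at-random (MAR) assumption, and a
delta-adjustment pattern-mixture sensitivity analysis under
missing-not-at-random (MNAR).

## The problem

When a patient experience program switches from interviewer-led
telephone surveys to self-administered mobile web surveys, scores can
shift for reasons unrelated to care quality: the modes recruit
different respondents and elicit different answers. In a randomized
mode experiment, patients are assigned 1:1 to the two modes, so the arms
are exchangeable; but with response rates far below 100% and unequal
between modes, the respondent contrast is biased for the causal effect.

The estimand is the average causal effect of mode over the full
randomized population,

    Δ = E[Y(mobile web)] − E[Y(telephone)],

on the 0–100 score of a 21-item questionnaire (South Korea's Patient
Experience Assessment convention: six domains, Likert/binary/0–10 items
each rescaled to a 100-point maximum). Three estimators are provided:

- **unadjusted** — respondent arm-mean difference, Welch inference;
- **ipw** — Hájek weighted contrast with weights 1/π̂ from a
  main-effects logistic response model, variance by the stacked
  M-estimation sandwich (weight-estimation uncertainty included);
- **mi** — per-arm Bayesian linear regression imputation (m = 50),
  all-patient contrast per copy, pooled by Rubin's rules
  (T = W + (1 + 1/m)B, classical t degrees of freedom).

The MNAR sensitivity analysis shifts imputed nonrespondent outcomes by
δ₁ (telephone) and δ₂ (mobile web) points over a grid (default −5…5 by
2.5). Under common random numbers the grid obeys the exact identity
Δ̂(δ₁,δ₂) = Δ̂(0,0) + δ₂·f_mob − δ₁·f_tel (f = arm missing fraction),
and `tipping_boundary()` locates sign and significance reversals.

A calibrated synthetic trial generator (`table1_margins_config()`)
reproduces the reference experiment's strata margins, mode-specific
response rates (22.4% / 32.5%) and respondent score distributions
(84.92 ± 14.34 / 81.51 ± 16.35), with known ground truth for validating
every estimator.

## Worked example

```r
library(pxamode)

cfg   <- table1_margins_config()          # calibrated 1600-per-arm design
trial <- generate_trial(cfg, seed = 20260927)
y     <- outcome_vector(trial, "total")   # 0-100 totals, NA for nonrespondents

unadjusted_difference(trial, y)
#> unadjusted mode effect on total (mobile web - telephone):
#>   -4.62 points (95% CI -6.54 to -2.69), SE 0.980, p = 2.919e-06, n = 884
ipw_difference(trial, y)
#> ipw mode effect on total (mobile web - telephone):
#>   -4.77 points (95% CI -6.76 to -2.79), SE 1.012, p = 2.439e-06, n = 3200
mi_difference(trial, y, m = 50, seed = 1)
#> mi mode effect on total (mobile web - telephone):
#>   -4.58 points (95% CI -6.67 to -2.48), SE 1.054, p = 3.811e-05, n = 3200
ground_truth(trial)$estimand
#> [1] -3.414016
```

The three estimators agree that this draw's mobile web arm scores about
4–5 points lower; the generating population contrast is −3.41 points,
within each interval. The sensitivity grid shows how the conclusion
depends on departures from MAR:

```r
g <- delta_grid(trial, y, m = 50, seed = 1)
g
#> Delta-adjustment grid for 'total' (m = 50, seed = 1)
#>         d2=-5.0 d2=-2.5 d2= 0.0 d2= 2.5 d2= 5.0
#> d1=-5.0   -4.10   -2.41   -0.72    0.97    2.66
#> d1=-2.5   -6.03   -4.34   -2.65   -0.96    0.73
#> d1= 0.0   -7.96   -6.27   -4.58   -2.89   -1.20
#> d1= 2.5   -9.89   -8.20   -6.51   -4.81   -3.12
#> d1= 5.0  -11.81  -10.12   -8.43   -6.74   -5.05
head(tipping_boundary(g)$sign, 3)
#>     axis fixed lower upper  crossing
#> 1 delta2  -5.0   0.0   2.5  1.066531
#> 2 delta2  -2.5   2.5   5.0  3.917733
#> 3 delta1   2.5  -5.0  -2.5 -3.743101
```

The mode effect stays negative except when telephone nonrespondents
are assumed to score much lower than telephone respondents (δ₁ ≤ −2.5)
*and* mobile web nonrespondents higher (δ₂ > 0); e.g. at δ₁ = −5 the
sign flips only once δ₂ exceeds about 1.1 points.

Descriptive and secondary analyses follow the same pattern:
`response_rate_table(trial)` (counts, percentages, chi-square tests),
`results_table(trial)` (all seven outcomes by all three methods),
`subgroup_analysis(trial, y, "sex")` (per-level estimates plus
interaction tests), and

```r
required_sample_size(difference = 1, sd = 2, power = 0.80, alpha = 0.05)
#> [1] 64
```

the noncentral-t per-group sample size for the design's 1-point,
SD-2 detection target.

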