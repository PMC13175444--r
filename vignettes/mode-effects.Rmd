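---
title: "Estimating survey mode effects under nonresponse: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating survey mode effects under nonresponse: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pxamode)
```

## The problem

Patient experience surveys are moving from interviewer-administered
telephone calls to self-administered mobile web questionnaires. The two
modes differ both in *who responds* (differential nonresponse) and in
*how respondents answer* (measurement effects such as social
desirability and acquiescence under an interviewer). When scores feed
public reporting or payment, a mode switch can shift a hospital's score
with no change in underlying experience.

`pxamode` analyzes a two-arm randomized mode experiment in the style of
South Korea's Patient Experience Assessment (PXA): discharged adult
inpatients are randomized 1:1 to a telephone or a mobile web
administration of the same 21-item questionnaire. Randomization
guarantees the arms are exchangeable at assignment; the analytical
problem is that only a minority respond, and response propensity
differs by mode and by patient characteristics.

The estimand is the average causal effect of mode on the 0–100 score
over the *full randomized population*,
$\Delta = E[Y(\text{mobile web})] - E[Y(\text{telephone})]$,
not merely the respondent contrast.

## Scoring

The PXA questionnaire has six domains — nurse (q1–q4), doctor (q5–q8),
medication and treatment (q9–q13), hospital environment (q14–q15),
patient's rights (q16–q19), overall ratings (q20–q21). Most items are
4-point Likert; q13 is binary yes/no; q20–q21 are 0–10 ratings. Every
item is rescaled so its maximum is worth 100 points, and the total and
domain scores are the rescaled sums (equivalently, means of the 0–100
item scores).

One convention is genuinely open: the published description fixes the
*maximum* at 100 but not the Likert anchor. We map Likert category
$v$ to $(v-1)/3 \cdot 100$, i.e. the minimum category scores 0, because
only this choice makes Likert, binary (yes = 100 / no = 0) and 0–10
(10·v) items commensurate with a common 0 floor and 100 ceiling. The
map is isolated in `rescale_item()` so an alternative anchoring (e.g.
25/50/75/100) is a one-line swap. Only complete responders are scored
(no partial-domain scoring), matching the analysis set of a survey in
which a "response" means answering every item.

## The three estimators

**Unadjusted.** Difference in respondent arm means with Welch
(unequal-variance) two-sample inference. The arm SDs genuinely differ,
and the Welch reference costs nothing; a pooled-variance t would be an
unstated extra assumption. This estimates the respondent contrast, not
$\Delta$, unless data are missing completely at random.

**IPW.** The response indicator is modeled by main-effects logistic
regression on mode, sex, age group, field of care and hospital;
respondents are weighted by $w_i = 1/\hat\pi_i$ and each arm mean is
the Hájek (normalized) weighted mean. Under MAR given those strata,
this consistently estimates $\Delta$. The variance comes from the
stacked M-estimation sandwich over the logistic score equations and the
two weighted-mean estimating equations, so the uncertainty of the
estimated weights is propagated; the CI uses the normal reference, as
the sandwich is asymptotic. Hájek normalization makes the contrast
invariant to rescaling all weights, which is also a cheap correctness
check.

**MI.** Within each arm separately, a Bayesian linear regression of the
observed outcome on the four strata (noninformative prior) generates
$m = 50$ posterior-predictive imputations of the missing outcomes; each
completed dataset yields the all-patient arm-mean difference, and
copies are pooled by Rubin's rules,
$T = W + (1 + 1/m)B$, with the classical degrees of freedom
$\nu = (m-1)\left(1 + \tfrac{W}{(1+1/m)B}\right)^2$. We use the
classical rather than the Barnard–Rubin small-sample $\nu$ because
$n \gg m$ in this design. Fitting the imputation model per arm (rather
than pooling with a mode covariate) matches the MAR statement — the
nonrespondent outcome distribution is assumed equal to the respondent
one *within each stratum of mode × covariates* — and is what makes
arm-specific delta shifts well-defined. Predictors are strata main
effects, not the 64-cell saturation: respondent counts per joint cell
are far too small to saturate, and the generator's outcome model is
itself additive, so this is also correctly specified in validation.

IPW and MI are complementary: IPW trusts the response model, MI trusts
the outcome model. Agreement between them is itself evidence the MAR
adjustment is not artifactual.

## Delta adjustment and tipping points

MAR is untestable, so the MNAR sensitivity analysis uses the
delta-adjustment pattern-mixture device: nonrespondent means are
assumed shifted by $\delta_1$ (telephone) and $\delta_2$ (mobile web)
points relative to respondents with the same covariates. This is
implemented inside MI — after drawing each imputation, the arm's delta
is added to every imputed value — and the estimate is recomputed over a
grid, by default $\delta \in \{-5, -2.5, 0, 2.5, 5\}$ on each axis
(the plausibility range is $\pm 5$ points on the 0–100 scale; 2.5-point
steps include the half-way scenarios commonly discussed).
$(\delta_1, \delta_2) = (0, 0)$ reproduces the MAR MI analysis exactly.

All grid cells share one seed, i.e. common random numbers: the
underlying posterior draws do not depend on delta, so

$$\hat\Delta(\delta_1, \delta_2) = \hat\Delta(0, 0) +
  \delta_2 f_{\text{mob}} - \delta_1 f_{\text{tel}},$$

*exactly*, where $f_a$ is the arm's missing fraction. This identity
makes the grid smooth, isolates the delta effect from Monte Carlo
noise, and gives closed-form tipping points: `tipping_boundary()`
reports adjacent cells where the estimate changes sign (with the exact
interpolated crossing) and where the 95% CI stops excluding zero.
Because the identity requires additivity, imputed values are *not*
clipped to [0, 100] by default; a `clip` flag exists for users who
prefer bounded imputations and accept an approximate grid.

## The synthetic trial generator

No individual-level data from the reference experiment are available,
so validation rests on a generator whose defaults reproduce that
study's conditions:

- **Strata.** Sex, age group (19–39, 40–59, 60–69, 70+), field of care
  (medical vs surgical/other) and hospital (A–D) are drawn
  independently with marginal frequencies equal to the published
  randomized denominators (e.g. 878/3200 aged 70+). The joint
  distribution is unpublished; independence is the neutral choice.
- **Response.** A main-effects logit on arm plus the four strata,
  fitted by randomized-count-weighted least squares to the published
  level-by-arm response rates, with intercept and arm coefficient then
  root-solved so the overall arm rates are *exactly* 358/1600 (22.4%)
  and 520/1600 (32.5%) in expectation. A main-effects model cannot hit
  every published cell — the oldest age group reverses the mode gap,
  an arm-by-age interaction — but it is the same model family the
  estimators assume, which keeps parameter-recovery well-posed.
- **Outcome.** A latent 0–100 total equal to a linear predictor plus
  Gaussian noise, censored to [0, 100]. Stratum effects are modest and
  chosen once (higher scores at older ages, small sex, care-field and
  hospital effects); per-arm intercepts and residual SDs are then
  solved so the *respondent* mean (SD) of the computed total equals
  84.92 (14.34) for telephone and 81.51 (16.35) for mobile web. The
  calibration accounts analytically for censoring (censored-normal
  moments) and for item discretization (below).
- **Items.** Each respondent's 21 raw items are generated by
  *stochastic rounding* of the latent total onto each item's legal grid
  (and a Bernoulli(latent/100) draw for q13), so the rescaled total is
  an exactly unbiased, discretized realization of the latent score.
  The added discretization variance is computable and is included in
  the SD calibration.
- **MNAR.** Nonrespondents' latent outcomes are shifted additively by
  the arm's true delta after censoring (no re-censoring), mirroring the
  delta-adjustment model exactly, so the grid cell at the generating
  shifts is consistent for the truth.
- **Seeds.** One master seed with deterministic per-stage child streams
  (strata, outcome, response, items); the same seed reproduces the
  dataset byte-for-byte.

Because the latent outcome is censored, the latent arm coefficient is
not the population mean contrast; `ground_truth()` therefore returns
both the generating parameters and `estimand`, the analytically
computed population contrast that the adjusted estimators target.

What the generator does *not* emulate: item-level response styles
(extreme responding, acquiescence at the item level), within-domain
correlation structure beyond the shared latent score, call-attempt
dynamics, and any arm-by-covariate interaction in response or outcome.
Passing recovery tests therefore show the estimators are correct under
the stated model, not that the model captures every feature of real
survey data.

## Numerical choices and degenerate inputs

- Reference coding everywhere uses the alphabetically first factor
  level; estimates are invariant to coding, so the rule only pins down
  reproducibility.
- Propensity fits with all-or-none response in any factor level stop
  with a separation error naming the level; fitted probabilities at
  the numerical boundary are also refused.
- An arm with fewer respondents than imputation-model parameters, or a
  stratum level with respondents absent in an arm, stops with an error
  rather than silently dropping predictors.
- Rubin pooling with zero between- and within-variance is an error;
  zero between-variance alone falls back to the normal reference.
- The sample-size helper iterates the noncentral-t power formula to the
  smallest integer n per group; the normal approximation (which gives
  63 where the t iteration gives 64 for a 0.5-SD effect at 80% power)
  is used only as a test oracle.
- Two-decimal table formatting rounds half away from zero, matching
  the usual printed-table convention rather than banker's rounding.

## Validation design and problem sizes

The test suite validates every estimator against an independent route:
hand-computed Hájek means and a delete-one jackknife for the IPW
sandwich; a closed-form two-copy oracle for Rubin's rules; the squared
two-proportion z identity for the chi-square; numerical integration for
the censored-normal moments; and `power.t.test` for the sample-size
iteration. Simulation checks use the calibrated design at its original
size (1600 per arm): 500 MAR replicates for bias and CI coverage of
IPW and MI (m = 10 imputations per replicate to keep the suite fast;
m = 50 is the analysis default) and for the type-I error of the
subgroup interaction test, and 200 MNAR replicates for recovery at the
generating delta pair. The delta-grid identity is checked at m = 50 on
the full 3200-patient design.

## Limitations

- The generator's independence and main-effects assumptions are a
  simplification of the real design; published cell rates with
  interactions (the 70+ reversal) are reproduced only in their
  main-effects projection.
- Delta shifts are constant within arm; individually varying deltas
  (e.g. by self-reported status) are out of scope.
- No doubly robust (AIPW) estimator, weight trimming, or multiplicity
  adjustment across the seven outcomes; per-outcome p-values are
  reported as-is.
- The scoring anchor for Likert items is a documented convention, not
  a published fact; swapping it changes score levels but not the
  structure of any estimator.
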