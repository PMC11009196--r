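---
title: "Frailty indices versus single biomarkers: models and design notes"
author: "frailtymark"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Frailty indices versus single biomarkers: models and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(frailtymark)
```

This vignette is the package's account of its statistical machinery: the
deficit-accumulation model, the nested-model AUC comparison, the weighted
DeLong-type test, the Benjamini–Hochberg screen, and the synthetic cohort
generator, together with the numerical conventions and design decisions a
user auditing results will want to know.

## The deficit-accumulation model

A frailty index treats health as the proportion of things that have gone
wrong. Each biomarker is mapped to a *deficit* value in $[0,1]$ by a
dictionary rule of one of three kinds:

* **binary normal-range**: 0 if the raw value lies inside the clinical
  normal range, 1 outside. We treat the range boundaries as *inside* the
  normal range (a value exactly at the bound codes to 0); inclusivity is a
  convention the underlying definition leaves open, and we fix it once.
* **ordinal**: ascending cut-points mapped to increasing deficit levels.
  A value equal to a cut-point belongs to the *higher* deficit level
  (left-closed intervals on the deficit-increasing axis).
* **normalized**: min–max rescaling between two reference values, with a
  direction flag; values outside the reference interval are clamped to 0
  or 1, not rejected — "does not saturate too early" is a criterion for
  *selecting* deficits, not a runtime constraint.

Non-numeric raw entries are treated as missing with a warning rather than
an error, since stray text in one cell of a 30,000-row table should not
abort a pipeline run.

For participant $i$ with deficit values $x_{i1},\dots,x_{ik}$ over a
considered item set, the FI is

$$\mathrm{FI}_i \;=\; \frac{\sum_{j\,\text{non-missing}} x_{ij}}
                          {\#\{j\,\text{non-missing}\}},$$

defined only when the completeness fraction (non-missing / considered) is
at least $0.8$. The threshold is inclusive and evaluated against the
considered set — so the leave-one-out FI used in Models 3 and 4 requires
80% of 22 (blood) or 46 (examination) items — and no rounding is applied
to the fractional threshold. An undefined FI is an explicit `NA`, never a
silent 0, so downstream sample restriction stays auditable.

## The four-model comparison

For each focal biomarker we fit, on one common complete-case sample, four
weighted logistic models of the binary death indicator: (M1) age + sex;
(M2) age + sex + biomarker; (M3) age + sex + leave-one-out FI; (M4) all
of them. Conventions:

* The biomarker enters M2/M4 **on its raw scale as a single linear
  term**. Nothing in the design fixes a transformation, and AUC is
  invariant to the coefficient scale; the raw-linear choice is the
  simplest documented assumption.
* Sex is coded female = 0, male = 1; age enters in years untransformed.
* The common sample requires non-missing age, sex, weight, outcome and
  focal biomarker, plus a *defined* leave-one-out FI. All four models —
  and all four AUC contrasts — use exactly this set, so differences in
  AUC are never artefacts of differing samples.
* Fitting maximizes the weight-multiplied Bernoulli log-likelihood via
  IRLS (`stats::glm`, quasibinomial family so non-integer analytic
  weights are accepted; the point estimates equal the weighted Bernoulli
  MLE). Convergence tolerance is $10^{-8}$ on the relative deviance
  change with at most 100 iterations. Separation is detected (diverging
  coefficients or fitted risks at the boundary) and flagged, not
  truncated. Rank-deficient designs are an error.
* Analytic weights are treated as importance weights in the likelihood.
  No design-based coefficient standard errors are produced: the
  inferential surface is the AUC comparison, not the coefficients.

## Weighted AUC and the DeLong-type equality test

The weighted AUC is the weighted Mann–Whitney statistic
$$\widehat{A} = \frac{\sum_{i \in D}\sum_{j \in \bar D} w_i w_j\,
\psi(s_i, s_j)}{\left(\sum_{i \in D} w_i\right)\left(\sum_{j \in \bar D}
w_j\right)},\qquad
\psi = \begin{cases}1 & s_i > s_j\\ 1/2 & s_i = s_j\\ 0 & s_i <
s_j,\end{cases}$$
computed through per-observation *placements* (a rank-based sweep
equivalent to the double sum; ties get half credit via midranks in both
the AUC and the placements). The weighted means of the event-side and
non-event-side placements both equal $\widehat A$ exactly, which the test
suite asserts as an algebraic identity.

For $k$ correlated score vectors on the same sample, the covariance of
the AUC estimates combines the weighted empirical covariances of the two
placement sets, each scaled by an effective sample size:

$$\widehat{\mathrm{Cov}} = \frac{S_{10}}{m_\mathrm{eff}} +
\frac{S_{01}}{n_\mathrm{eff}},\qquad
m_\mathrm{eff} = \frac{(\sum_{i\in D} w_i)^2}{\sum_{i\in D} w_i^2}.$$

Two deliberate choices here:

* **Kish effective sizes.** A plain sum of weights is not invariant to
  rescaling all weights by a constant — which would contradict the
  estimator's own invariance (AUC and the test statistic must not change
  when weights are rescaled) — and understates the variance of a weighted
  mean. The Kish form $(\sum w)^2/\sum w^2$ is scale-invariant, is the
  first-order correct scaling for weighted means under independent
  observations, and reduces exactly to the classical DeLong $m$ and $n$
  under unit weights. Because no closed-form reference exists for the
  analytic-weight case, the estimator is validated against a
  2,000-replicate bootstrap in the test suite.
* **Weighted Bessel correction.** The placement covariances divide by
  $\sum w - \sum w^2/\sum w$, which reduces to $m-1$ at unit weights, so
  the unit-weight path is bit-for-bit classical DeLong (cross-checked
  against an independent implementation in the tests).

The equality test for a pair is $\chi^2 = (\widehat A_a - \widehat
A_b)^2 / \widehat{\mathrm{Var}}(\widehat A_a - \widehat A_b)$ on 1 df. A
numerically zero variance with equal AUCs (identical score vectors) is a
null comparison ($\chi^2 = 0$, $p = 1$); zero variance with unequal AUCs
is an error, since the contrast is ill-posed. A joint $k$-model contrast
test on $k-1$ df is provided for completeness, but the pipeline's
inference is pairwise throughout, matching the four pairwise model
contrasts. Confidence intervals are Wald on the AUC scale truncated to
$[0,1]$ by default, with a logit-scale option.

## Multiple testing

Each panel × contrast family (23 or 47 p-values) is screened with the
Benjamini–Hochberg step-up rule at FDR $q = 0.05$: rank-$i$ critical
value $i/m \cdot q$, reject the prefix up to the largest rank whose
p-value passes, ties share a fate. The family definition — one contrast
type across one panel's biomarkers — is the narrowest reading consistent
with per-column significance marks in a two-table summary; since the
grouping is genuinely open, a pooled all-rows family is available as a
sensitivity switch (`family_mode = "pooled"`). The implementation is the
critical-value form and is cross-checked against the adjusted-p
formulation (`p.adjust(..., "BH")`) on random vectors in the tests.

## The synthetic cohort generator

The generator exists because the motivating cohort is restricted-access:
it emulates the *statistical structure* the analysis assumes, so the full
pipeline is testable end to end. It is calibrated to published population
marginals, all deterministically:

* **Age** (years): truncated normal on $[45, 85]$. The underlying normal
  parameters are moment-matched (closed-form truncated-normal moments +
  optimization) so the *realized* distribution has mean 59.4 and SD 9.9;
  naive truncation of $N(59.4, 9.9^2)$ would inflate the mean by over a
  year.
* **Sex**: Bernoulli, 50.3% female.
* **Latent vulnerability**: one standard-normal factor per participant,
  shared by all deficits and by mortality. A single factor is the
  simplest structure producing the phenomenon under study — that an
  aggregate of weakly informative deficits out-predicts any single one.
* **Biomarkers**: each item's deficit propensity is logistic in age (0.3
  log-odds per decade) and the latent factor (loading 0.5), with an
  item-specific noise term (SD 1.2) for the continuous examination
  severities. Raw values are constructed to *invert the coding rule
  exactly* (deficit blood values sit just outside the normal range;
  normalized severities are mapped back through the min–max transform),
  so coding a generated cohort reproduces the intended deficit
  distribution with no leakage. Per-panel intercepts are solved by
  deterministic quadrature (128 × 128 quantile-midpoint grid over the
  age and normal components) so the expected mean deficit equals the
  target exactly: 0.15 per blood item, 0.27 per examination item — which
  makes the expected FI-Blood and FI-Examination means 0.15 and 0.27 by
  construction. All items within a panel share the target, so a column's
  distribution depends only on its own rule and random substream.
* **Mortality**: logistic in age per decade (0.9), male sex (0.4) and
  the latent factor (0.6); the intercept is calibrated by monotone
  root-finding so the expected weighted prevalence hits the 3.1% target.
  The root-finder works on the *expected* prevalence given a pilot draw
  of covariates (the mean of `plogis` over pilot linear predictors),
  which is smooth and strictly increasing in the intercept, rather than
  on realized Bernoulli deaths — same target, far less Monte-Carlo
  noise. The default coefficients give a true-model AUC near 0.78,
  consistent with the discrimination reported for comparable cohorts.
* **Missingness**: 10% of participants lose their entire blood panel
  (no blood sample), and 2% of remaining cells are punched out
  independently. Both mechanisms are completely at random — the
  motivating study reports no missingness mechanism, so MCAR is a
  stand-in, not a claim. Demographics, weights and the outcome are never
  made missing.
* **Weights**: unit by default; an optional scheme draws weights uniform
  on $[0.5, 2]$ normalized to mean 1, purely to exercise the weighted
  code paths. The real survey weights are consumed by the analysis, not
  modelled.
* **Seeding**: one root seed, with an independent named substream per
  column (age, sex, latent, each biomarker, death, each missingness
  layer), derived by hashing the stream name. Adding an item to the
  dictionary therefore cannot perturb any other column, and identical
  configs yield bit-identical tables.

What the generator does **not** emulate: the survey's stratified
sampling and weight construction, geographic structure, informative
missingness, item-level correlation beyond the single shared factor, and
time-to-event structure (the outcome is binary death by the censoring
date). Tests passing on synthetic cohorts therefore demonstrate the
*correctness of the machinery* and the qualitative FI-versus-biomarker
asymmetry under the assumed structure; they do not reproduce
restricted-data results such as specific per-biomarker AUCs or
check-mark counts.

## Problem sizes and test design

The test suite exercises the oracle equivalences at enumeration scale
(all weighted instances of ≤ 12 observations against the explicit double
sum; definitional placement covariances on small instances), the
frequentist properties at simulation scale (2,500 null replicates of
n = 300 for the equality test's size; a 2,000-replicate bootstrap at
n = 2,000 for the variance; 1,000 random p-vectors for the BH oracle),
and the calibration and qualitative headline at the full default cohort
size of n = 30,000. Smaller cohorts (n ≈ 2,500–3,500) are used where only
plumbing is under test. These sizes are the package's own choice of
where each property is informative.

## Known limitations

* The default dictionary's numeric cut-points are synthetic placeholders
  on plausible clinical scales; real analyses must supply a dictionary
  with validated cut-points (`read_dictionary()`).
* Coefficient-level inference is deliberately absent; if design-based
  standard errors are needed, fit the models with a survey package and
  feed the predicted risks into `auc_weighted()` /
  `test_auc_equality()`.
* The weighted DeLong variant assumes independent observations with
  fixed weights; clustered or calibrated survey designs would need a
  replication-based variance instead.
* With heavy ties and very small samples the chi-square reference for
  the equality test is approximate, as in any DeLong-type procedure.
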