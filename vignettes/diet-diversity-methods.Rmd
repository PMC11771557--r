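---
title: "Diet-diversity scoring and food-allergy association models: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diet-diversity scoring and food-allergy association models: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dietdiv)
```

## The scientific problem

Whether a diverse complementary diet in infancy protects against early food
allergy (FA) is a live question in paediatric allergy prevention. The
NorthPop birth cohort design that this package models asks it with three
diet-diversity (DD) measurements per infant, one of which — unusually —
weights foods by how often they are eaten, not just whether they have been
introduced:

* **Weighted DD score, 9 months, range 0–31.** For each of 14 foods the
  consumption-frequency category maps to points: never = 0, 1–3
  times/month = 1, weekly (1–6 times/week) = 2, and daily (1–6 times/day)
  = 1 for the eleven staple/animal foods but 3 for the three plant foods
  (fruit and berries, vegetarian meat substitutes, vegetables). The drop
  from 2 to 1 for daily staples encodes "more is not always better"; the
  3 for daily plant foods encodes the guideline to eat plant foods most
  frequently. The maximum of 31 (11×2 + 3×3) is attained exactly when
  every staple is eaten weekly and every plant food daily.
* **Introduced foods, 6 and 9 months, range 0–14.** A count of food groups
  introduced at all, regardless of frequency.
* **Introduced allergenic foods, 6 and 9 months, range 0–6.** The same
  count restricted to milk (the dairy item: any cow's-milk product
  excluding formula), wheat, egg, fish, soy, and nuts/peanuts.

Introduction timing is recorded on a four-level scale (not introduced by
around 9 months / 0–3 months / 4–6 months / 7 months or later);
"introduced by 6 months" means the 0–3 or 4–6 category, "introduced by
9 months" anything except "not introduced". Each score is missing whenever
any of its items is missing — no imputation anywhere in the package, which
mirrors the complete-case design of the source analysis.

One published ambiguity deserves a note: the score table lists rice with
the 0–2-point cap but marks it with the plant-food footnote. Only the
eleven-staples reading reproduces the printed total range of 31, so rice is
a staple by default; `dd_scheme("weighted", rice = "plant")` exposes the
alternative reading (maximum 32).

## Association models

The central fitting function `dd_assoc()` estimates the DD–FA association
by maximum-likelihood logistic regression on the complete cases of the
model's own variable set (score items, outcome, covariates). Exposures
enter either continuously (per-point odds ratio) or as the published
four-group categorisations, indicators against the lowest-diversity
reference group. Two DAG-derived adjustment sets are built in:

* **Model 1** (minimal sufficient set): maternal ethnicity, maternal
  university education, breastfeeding status at 4 months, early (< 4
  months) introduction of solids.
* **Model 2** adds family FA history, outdoor living environment, and
  maternal age at delivery.

Covariate reference levels are the majority levels (Sweden-born, exclusive
breastfeeding, city); exposure odds ratios are invariant to this choice.

The published table does not state its interval method. Confidence
intervals and p-values here are Wald/Woolf: for a 2×2 table with cells
$a,b,c,d$,

$$\widehat{OR} = \frac{ad}{bc}, \qquad
  SE = \sqrt{\tfrac1a + \tfrac1b + \tfrac1c + \tfrac1d}, \qquad
  CI_{95} = \exp\{\log \widehat{OR} \pm z_{0.975}\,SE\},$$

with the two-sided p-value from the normal tail of $\log\widehat{OR}/SE$.
This choice is not arbitrary: it reproduces the published unadjusted
category estimates at printed precision (e.g. 0.47 (0.22–1.00), p = .051
for the top weighted-score group), which the acceptance tests verify row by
row from the published counts. The multivariable fits use `stats::glm`
with its default IRLS convergence tolerance; Wald intervals come from the
coefficient and its standard error, so the unadjusted categorical logistic
estimates agree with the closed-form 2×2 estimates to numerical precision
— a dual-route check the test suite enforces at tolerance 1e-6.

Degenerate situations are flagged rather than silently estimated: zero
cells in a 2×2 table (no continuity correction), exposure levels with zero
cases (their records are dropped from the fit so the remaining contrasts
stay estimable), constant exposures, separation (|coefficient| > 15 or
SE > 1000), and non-convergence.

`run_table3()` fits all five exposure blocks × two forms × three
adjustment sets (30 fits); `run_sensitivity()` re-runs them after excluding
9-month FA diagnoses (reverse causality) or FA cases with only
gastrointestinal symptoms (diagnostic misclassification);
`run_stratified()` fits model 2 within strata of family FA history or
eczema for the two 9-month exposures. Records with a missing stratifier
are excluded from stratified fits and counted. No multiple-testing
adjustment is applied, matching the source design. P-values render in the
source style (".051", "<.001") only at printing; stored values keep full
precision.

## The synthetic cohort: what it emulates

The study's individual-level data are not public, so the generator is the
package's test bed. Its defaults *are* the published study conditions:

* **Covariates** follow the published cohort characteristics (49.7% girls;
  feeding at 4 months 65.0/15.7/16.6%; 12.8% early solids; 27.4% family FA
  history; 28.9% eczema; 68.4% maternal university education; 7.7%
  non-Swedish origin; outdoor environment 61.2/19.0/19.8%; maternal age
  31.3 (SD 4.3) years). Category probabilities are conditioned on the
  published per-field missingness so the realized fractions of the whole
  cohort match the published percentages after masking.
* **Frequency items** are calibrated by `calibrate_ffq_profile()` so the
  implied weighted-score mean and SD equal the published 19.77 (3.91)
  *exactly*, using the closed form: the score mean is the sum of per-food
  expected points and the variance the sum of per-food point variances
  under independence. A deterministic grid search over the two per-class
  moment parameters picks, among all exact solutions, the least bimodal
  per-food distributions. Matching an SD of 3.91 with 14 bounded
  independent items still forces strongly bimodal items (a sum of
  independent 0–2/0–3-point items cannot otherwise be that dispersed);
  real FFQ items achieve the spread through correlation instead, which is
  why an optional latent loading (`ffq_rho`) exists for robustness
  scenarios.
* **Timing items** are calibrated by `calibrate_timing_profile()`:
  per-food base introduction propensities are shifted on the logit scale
  (one scalar per food group and age, solved by `uniroot`) so the four
  introduction-score means equal the published 8.99 / 11.53 / 2.94 / 4.13
  exactly. The published SDs (2.81 / 1.51 / 1.44 / 1.06) are *not*
  attainable under independent items — a sum of 14 Bernoulli variables
  with mean 8.99 has SD at most 1.87 — so timing items share one latent
  "diet propensity" factor through a Gaussian copula, which preserves
  every marginal (hence every mean) and inflates the spread. The loading
  is chosen once by deterministic least squares against the four SDs,
  using closed-form pairwise probabilities (a one-dimensional quantile
  integral); the compromise value ≈ 0.45 yields implied SDs of about
  2.48 / 1.82 / 1.52 / 1.34. The split of by-6-month introductions into
  0–3 vs 4–6 months uses fixed food-specific shares; no score depends on
  that split.
* **The outcome** is drawn from a planted logistic model whose linear
  predictor uses each infant's *own generated weighted score computed by
  the real scoring code*, centred at its implied mean so the intercept
  anchors prevalence at the typical diet: per-point slope `log(0.96)` by
  default (the magnitude of the fully adjusted continuous estimate), the
  published predictor odds ratios for family FA history (2.51) and
  feeding mode (1.77 partial, 1.89 formula), and an intercept calibrated
  by closed-form expectation (score pmf by exact convolution ×
  family × feeding) to a marginal 4.9% prevalence. The 9-month diagnosis
  is a sub-event of the 18-month outcome with a 73% early fraction
  (published 73 of 100 cases), and 33% of cases carry the
  gastrointestinal-only flag.
* **Missingness** is applied last, as pure masking, so regenerating with
  all rates zero and the same seed returns the complete data. Rates
  follow the published per-field missingness, with one structural choice:
  the pregnancy-questionnaire covariates go missing *together* (ethnicity
  and university education jointly, family history mostly nested inside
  that block). That co-missingness is the only structure consistent with
  the published complete-case flow 2060 → 1960 (model 1) → 1957
  (model 2) alongside the per-field counts; under it the expected flow is
  ≈ 1959 → 1956.

Because the FFQ items stay independent by default (to keep the
weighted-score SD exactly at 3.91), the weighted and introduction scores
are uncorrelated unless `ffq_rho > 0` — a deliberate simplification: one
identified causal path (weighted score → outcome) keeps the recovery
experiments interpretable. Eczema and family history are plain covariates
by default; effect-modification scenarios switch on stratum-specific
slopes (`modifier_field`, `modifier_slopes`) and typically also a main
effect of the modifier (`or_modifier`), since in reality eczema is itself
a strong FA predictor and a stratum needs cases before a within-stratum
slope is estimable.

## What the simulations do and do not show

`parameter_recovery_experiment()` repeatedly generates, scores, and fits
the fully adjusted continuous model. The test suite uses it four ways:
equality of unadjusted categorical logistic ORs with the closed-form 2×2
oracle on 50 synthetic cohorts (tolerance 1e-6); recovery of a planted
slope of −0.05 within ±0.02 at n = 200,000 (10 replicates); 95% Wald CI
coverage within 95% ± 2.5% over 500 replicates at n = 2060; and type-I
error within 5% ± 2% under a null slope over 1000 replicates. These
validate the estimation machinery under a correctly specified model with
missingness completely at random. They do not — and cannot — validate
against informative missingness, correlated food items beyond the single
latent factor, residual confounding, or reporting bias in
parent-reported diagnoses; conclusions about real cohorts inherit those
caveats from the design, not from this implementation.

Problem sizes for the routine runs were chosen to keep the full suite in
the low minutes on one core while leaving the binomial error of each check
well inside its tolerance band: 30 seeds for generator margins, 500
coverage replicates, 1000 type-I replicates, 10 large-n recovery
replicates, 200 replicates for the stratified effect-modification check.

## Numerical choices and edge cases

* Intervals use `qnorm(0.975)`, not 1.96; at printed precision both
  reproduce the published cells.
* `glm` numerical warnings (fitted probabilities 0/1) are captured as
  flags on the result object rather than escaping as warnings.
* Category codes outside their scale become missing on read, with a
  counted warning; duplicated or empty infant ids are hard errors.
* A gastrointestinal-only flag without an 18-month FA diagnosis violates
  an invariant and is set to missing with a warning.
* Exclusion filters are idempotent and log `(rule, n_removed, n_after)`;
  every reported `n_used` reconstructs from the log.
* Score values outside their scheme's range raise an error at
  categorisation (an invariant breach upstream, never silently binned).
* The calibration grid solves the two moment equations exactly; an
  infeasible mean/SD pair raises an error naming the feasible SD envelope
  at that mean.

## Known limitations

* Items within an infant are conditionally independent given one latent
  factor; real diets have richer correlation (food-group clusters,
  cultural patterns).
* The four published introduction-score SDs cannot all be matched by a
  single loading; the calibrated compromise overshoots the 9-month SDs
  and undershoots the 6-month ones.
* The published table's printed p of .913 for the 18–20p unadjusted row is
  not reproducible from its own printed counts (the Woolf p is .728, while
  the printed OR and CI reproduce exactly); three further cells differ by
  one unit in the last printed digit. The shipped reference table flags
  these cells and the tests treat them accordingly.
* Adjusted (model 1/2) published coefficients are not reproducible without
  individual-level data; the adjusted machinery is therefore validated by
  simulation, not against printed adjusted estimates.
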