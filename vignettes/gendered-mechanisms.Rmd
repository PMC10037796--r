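---
title: "Gendered mechanisms behind sex differences in biomarkers: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gendered mechanisms behind sex differences in biomarkers: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gendermech)
```

## The scientific question

Men and women differ, on average, in many of the biomarkers used to measure
allostatic load — systolic blood pressure, serum lipids, HbA1c, CRP,
cortisol. Such differences are often attributed wholesale to sexual
dimorphism. gendermech implements a counterfactual framework for asking how
much of each difference is instead attributable to *gendered* mechanisms:
social characteristics and behaviours that are differentially distributed by
sex at birth and that themselves affect biology.

Gender is operationalized in three complementary ways, each with its own
estimand:

- **(a) Gender as an individual characteristic.** A *gender score* G is the
  predicted probability of being male-born from a logistic regression of sex
  on socio-behavioural characteristics ("gender diagnosis"). Blocking this
  pathway means fixing everyone's score at a common value g0:
  `CDE^G = E[Y(S=1, G=g0)] - E[Y(S=0, G=g0)]`.
- **(b) Gender as the effect of sex on socio-behavioural characteristics.**
  The mediators are the characteristics themselves, fixed jointly at a
  reference profile epsilon*:
  `CDE^Sigma = E[Y(S=1, Sigma=eps*)] - E[Y(S=0, Sigma=eps*)]`.
- **(c) Gender as a sex-by-environment interaction.** If the sex gap varies
  across social strata, that variation is itself evidence of gendered
  construction. The remaining effect is the sex gap in the non-deprived
  stratum, `TE^0`, and the additive interaction
  `IE = E[Y(1,1) - Y(1,0) - Y(0,1) + Y(0,0)]` summarizes the
  effect-modification.

Each strategy reports an *eliminated proportion*
`EP = (TE - remaining) / TE`, where `TE = E[Y(S=1) - Y(S=0)]` is the total
effect of sex at birth. Negative EPs are meaningful: they say the sex gap
*widens* when the gendered pathway is blocked (attenuation).

## Estimation

All counterfactual means are estimated by the parametric g-formula
(g-computation). A linear outcome regression `Qbar(A, L)` is fitted by
ordinary least squares; predictions with the scenario assignments
substituted are averaged over all cohort members, standardizing empirically
over the unassigned covariates. Three covariate specifications are used and
all contain sex S, early-life deprivation E and their product S:E:

- `S*E` — for TE, the stratum effects TE^e, deprivation effects by sex,
  cell means and IE. This model is saturated in (S, E), so every
  g-computed mean equals the corresponding observed cell mean; the
  decomposition identities `TE = P(E=0)·TE^0 + P(E=1)·TE^1` and
  `IE = TE^1 - TE^0` hold to machine precision and are enforced by tests.
- `S*E + G` — the gender score enters linearly, with no S:G product. The
  linearity is the simplest reading of a model in (S, G, E); because there
  is no S:G term, the choice of g0 cancels in the CDE contrast exactly
  (also a tested invariant). The default g0 = 0.5 is the midpoint of the
  femininity-masculinity continuum.
- `S*E + Sigma` — mediators enter as binary main effects, no S:Sigma
  products, so the reference profile epsilon* likewise cancels in the
  contrast. The default epsilon* fixes each mediator at its modal category
  in the analysis dataset; any published profile can be supplied instead.
  (Binary mediators need no further coding; a quantitative mediator would
  enter linearly.)

Outcomes are analysed on their native scale (mmHg, g/L, ...) and as
z-scores `z = (y - mu)/sigma`, where mu and sigma are the mean and SD of
the outcome *in the dataset at hand* — inside the bootstrap, each
replicate's own moments. Right-skewed markers (triglycerides, CRP,
cortisol) are modelled on the natural-log scale throughout; the log base
is a reporting convention only, since EPs are ratios and z-scores are
scale-free.

### Eliminated proportions near a null total effect

EP divides by TE, so it explodes when TE is near zero (cortisol is the
canonical case: tiny TE, enormous EP intervals). The package still reports
these EPs — suppressing them would misrepresent the method — but a TE of
exactly zero yields `NA` with an `undefined` flag rather than an error,
and the tidy output carries the TE each EP was normalized by, so
downstream consumers can apply their own stability rule.

## The gender score

`fit_gender_model()` is a main-effects maximum-likelihood logistic
regression of sex on the active variable set. Three sets are predefined:
*complete* (all 21 registry variables), *behavioural* (the 8 behaviour
items), and *small* (4 social characteristics + 4 behaviours). More
variables make the score more discriminating; the male-female score gap
under the complete set exceeds the small-set gap, which the tests assert
on synthetic data.

Cohort-scale data will not separate, but toy and test tables do. On
detected separation (non-convergence, runaway coefficients, or fitted
probabilities at the boundary) the model is refitted with a small fixed
quadratic penalty (ridge, strength 0.1, intercept unpenalized) by Newton
iteration, and flagged — never silently. The fallback is verified against
a grid-search oracle of the penalized likelihood.

The score model is refitted inside *every* bootstrap replicate, after that
replicate's imputation, so score-estimation uncertainty propagates into
all percentile intervals.

## Missing data and inference

Inference follows a bootstrap-then-impute design: resample n individuals
with replacement, run a *single stochastic imputation* on the resampled
table, recompute everything (score model included). Point estimates are
replicate means; confidence intervals are the 2.5/97.5 percentiles (linear
interpolation of order statistics, R's type-7 rule). An interval touching
zero counts as non-significant. The headline B is 1,000; tests and the
acceptance script use B of 150–200, which is ample for the percentile
summaries they check.

The imputation is chained equations with regression draws, implemented in
the package: binary columns by logistic fit + Bernoulli draw, continuous
columns by least-squares fit + Gaussian residual draw, columns visited in
order of increasing missingness for a default of 10 cycles. Two deliberate
simplifications relative to full MICE-style samplers are part of the
contract: no posterior draw of the regression coefficients and no
predictive mean matching. Within-replicate uncertainty understatement is
absorbed by the bootstrap, which is the sole source of interval width.
Markers analysed on the log scale are imputed on the log scale (where the
Gaussian draw is coherent) and their native columns derived by
exponentiation, keeping the two representations consistent by
construction.

A complete-case option restricts the analysis to rows fully observed on
all analysis variables and never imputes; it proxies a sensitivity
analysis on fully-participating cohort members (true wave-attendance
indicators do not exist for synthetic data).

## The synthetic cohort generator

The generator is first-class, tested code: it emulates a mid-century
British birth cohort with known causal structure so every estimator can be
validated against closed-form truth.

- Sex at birth: Bernoulli(0.51).
- Environment: short maternal education (P = 0.75) and manual parental
  class (P = 0.73) drawn jointly with odds ratio 3 — social clustering
  makes the indicators correlate; independence would be implausible.
  Deprivation E is their conjunction (about 60% of the cohort).
- Mediators: `logit P(M_j = 1) = alpha_j + beta_j S + gamma_j E`. The
  (alpha, beta) defaults are calibrated so that prevalences by sex match
  the magnitudes observed in the cohort the package models (sex gaps from
  0.3 to 80 percentage points); the gamma defaults are modest deprivation
  shifts (|gamma| <= 0.6) in sociologically plausible directions. No
  published values exist for mediator-to-biomarker effects, so the w_j
  defaults are calibration choices: a handful of behavioural effects per
  biomarker sized so that mediation accounts for a few percent of each
  total effect, consistent with the reported eliminated proportions.
- Biomarkers: `Y = a + b S + c E + d S:E + sum_j w_j M_j + N(0, sigma_y)`,
  generated on the log scale for the skewed markers and exponentiated, so
  the analysis's log transform recovers exact linearity. Sex effects span
  0.1–0.75 SD and interactions are near -0.1 SD, matching the reported
  effect sizes.
- Missingness: per-column logistic MAR models whose predictors are
  restricted to always-observed columns (sex, environment); mediators
  around 10–12% missing, biomarkers 25–35%, slightly higher under
  deprivation. Masking a design column, or referencing a maskable column
  as a predictor (which would make the mechanism MNAR), is rejected.

`compute_truth()` returns the implied true estimands. TE, CDE^Sigma,
TE^e, IE and both EPs have closed forms obtained by marginalizing over E
and the mediator response to S (averages of inverse-logits); the marginal
SD used for z-scale truths is also closed-form. The score-based CDE^G has
no closed form — the score is a fitted compression of the mediators — so
its truth is a Monte-Carlo plug-in: simulate a large cohort (default
2×10^5), fit the score and outcome models on it, take the contrast, with
a Monte-Carlo SE from independent batch splits.

What the generator does *not* emulate: attrition and mortality selection,
longitudinal wave structure beyond "mediators before outcomes",
mediator-mediator causal ordering, and MNAR missingness. Passing tests
therefore demonstrate correctness of the estimators under a well-specified
linear data-generating process, not robustness to model misspecification
on real cohort data.

## Numerical and design choices

- **Seeds.** One master seed; child seeds for each stage (environment,
  mediators, outcomes, missingness, imputation, bootstrap replicate) are
  derived by fixed integer offsets, all below 2^31. Same seed, same
  output, byte for byte; replicates are seed-independent of execution
  order.
- **Sex coding.** Male-born = 1 everywhere, so the gender score reads
  "probability predicted male".
- **Deprivation conjunction with missing parents.** An observed 0 in
  either indicator settles the conjunction at 0; only (1, missing) and
  (missing, missing) remain missing, and are left to imputation rather
  than listwise deletion.
- **Degenerate inputs.** Empty sex-by-deprivation cells make the saturated
  model rank-deficient and are rejected naming the offending cell; single-sex
  tables are rejected by the score model; an all-missing column is rejected
  by the imputation; estimator failures inside the bootstrap are dropped and
  counted, with the run aborted beyond 5% failures.
- **Double-log guard.** `transform_outcomes()` refuses to run twice, and
  refuses non-positive values for log-scale markers, naming the rows.
- **Problem sizes.** The test suite runs recovery at 200 replicates of
  n = 10,000 (point estimators), 100 outer replicates with B = 200
  (coverage), and 200 replicates of n = 1,200 with reduced parameter sets
  (imputation recovery); the acceptance script analyses one cohort of
  n = 3,000 with B = 150 and 5 imputation cycles. These sizes give
  Monte-Carlo error well below the effects being checked while keeping a
  full run on one CPU comfortable.

## Known limitations

- The linear outcome models are correctly specified for the generator by
  construction; on real data, nonlinear mediator-outcome relations or
  sex-by-mediator interactions would bias the CDEs (the no-interaction
  assumption is what makes epsilon* and g0 cancel).
- EPs are ratio estimands and inherit the instability of their
  denominator; interpret cortisol-style EPs through their intervals.
- The bootstrap treats individuals as exchangeable; no survey weights or
  clustering.
- Strategy (c) identifies gendered mechanisms only insofar as gender
  processes genuinely differ between the environment strata; a population
  homogeneous in its gender norms yields IE near 0 regardless of how
  gendered it is overall.
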