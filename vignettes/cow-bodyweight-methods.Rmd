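---
title: "Predicting dairy-cow body weight from body measurements: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting dairy-cow body weight from body measurements: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cowbw)
```

## The problem

Body weight matters for feeding, health monitoring and breeding decisions
on dairy farms, but scales are rarely available outside performance
testing. Girth and width measurements taken with a tape or stick during
routine linear scoring are cheap substitutes. `cowbw` implements a
complete workflow around weight prediction from such measurements for the
breeds commonly milked in Austria -- Fleckvieh (a dual-purpose Simmental
type, including its Red Holstein crosses), Holstein-Friesian and Brown
Swiss -- across the whole production cycle, i.e. both lactation (days in
milk 1--364) and the dry period (days -56 to -1 before the next calving).

## The prediction model

A weighing record is modelled as

$$Y_{ijklm} = \mu + G_i + P_j + PS_k + \sum_l b_l X_l +
  \sum_l b_l(G_i) X_l + F_m + \varepsilon_{ijklm},$$

where $G_i$ is the genotype class, $P_j$ the parity class, $PS_k$ the
physiological stage, $X_l$ the body measurements with pooled slopes $b_l$
and genotype-specific slope deviations $b_l(G_i)$, $F_m$ a random farm
effect and $\varepsilon$ the residual. Reference coding sets Brown Swiss
(`BS`), the oldest parity class (`P5plus`) and all `BS` slope deviations
to zero, so pooled slopes are directly interpretable as the Brown Swiss
response and deviations as breed contrasts.

The classes are:

* **Genotype** -- `FV` (Fleckvieh with at most 10 % Red Holstein genes),
  `FV_RH_m` (>10--44.5 %), `FV_RH_h` (>44.5 %), `HF`, `BS`
  (`classify_genotype()`).
* **Parity** -- 1, 2, 3+4, and 5 or more (`classify_parity()`).
* **Physiological stage** -- thirteen 28-day lactation months covering
  days in milk 1--364 plus four 2-week dry stages covering days -56 to
  -1 (`stage_class()`). The lactation domain is taken as 1--364: the 13
  months span exactly $13 \times 28 = 364$ days, which is also the
  largest day observed in the population the equations derive from.

For prediction the categorical stage effect is replaced by continuous
curves fitted to the stage least-squares means: a fourth-degree
polynomial in days in milk for lactation and a straight line for the dry
period. Degree 4 is the smallest degree that avoids both the poor fit of
a quadratic and the premature curvature change of a cubic inside the
lactation window; the curves are deliberately not evaluated outside
their windows (the package raises an error instead), because polynomial
behaviour beyond the fitted range is meaningless.

Two published coefficient sets ship with the package as structured text
files: `bw_model("hgbg")` (heart girth + belly girth) and
`bw_model("hgbghw")` (+ hip width). Coefficients are stored exactly as
published, in kg and cm, without internal rescaling, so they can be
inspected and cross-checked directly. Predictions are made at population
level (farm effect 0), which is also how the equations are validated.

```{r packaged}
m <- bw_model("hgbghw")
stage_effect(c(-56, -1), "dry", m)
predict_bw(data.frame(genotype = "BS", parity_class = "P5plus",
                      day = 100, HG = 210, BG = 256, HW = 57), m)
```

## Re-estimating an equation

`fit_mixed()` re-estimates the model from weighing records by REML
(via `lme4`), then completes it into a usable equation:

1. the mixed model with the categorical stage effect is fitted;
2. `stage_lsm()` extracts the 17 stage least-squares means -- genotype
   and parity averaged with equal weight, measurements at their grand
   means, farm effect 0, matching the LSMEANS convention of the
   mixed-model software the published equations come from (computed with
   `emmeans`, asymptotic degrees of freedom; only the means are used);
3. `fit_stage_curves()` fits the lactation polynomial and the dry line
   to the LSMs by ordinary least squares at the class midpoint days
   (14.5, 42.5, ..., 350.5 and -49.5, -35.5, -21.5, -7.5 -- the
   symmetric choice; the abscissae are configurable);
4. `assemble_prediction_model()` merges everything into a
   `coefficient_set`.

Two estimation choices deserve a note:

* **No per-cow random effect.** Repeated records of one cow are treated
  as independent given the farm. Models with a cow effect were not
  estimable on the data the equations derive from, and the package
  mirrors that structure.
* **Kenward--Roger P-values are out of scope.** The package reports
  estimates, RMSE and the REML-based AIC (the figure the original
  software prints); fixed-effect significance testing is deliberately
  omitted rather than approximated differently.
* **Quadratic measurement terms** are available behind
  `model_spec(..., quadratic = TRUE)` for exploration but excluded from
  the packaged pipelines; they did not improve prediction in the source
  population.

### An identifiability convention

After the categorical stage effect is replaced by two fitted curves, the
model intercept and the two curve constants share one additive constant
that no data can separate (only the sums "intercept + lactation constant"
and "intercept + dry constant" are identified). `cowbw` resolves the
split by convention: the fitted stage values are centered to mean zero
across the 17 class-midpoint days and the remainder is absorbed into the
intercept. Predictions are invariant to this choice. Consequently, when a
re-fit is compared against a generating equation, all effects, slopes and
curve shapes are recoverable exactly, while the intercept/constant split
is recovered up to that convention.

`stepwise_evaluate()` ranks candidate measurement sets by fitted RMSE
(ties broken towards fewer measurements), with AIC reported alongside;
on data with the package's default generating structure the ranking
reproduces the expected ordering: heart girth alone beats any other
single trait, adding belly girth and then hip width reduces the RMSE
further.

## Validation

`split_every_fifth()` reproduces the deterministic 80/20 hold-out rule:
records are sorted by cow identification number -- with day relative to
calving and input order as secondary keys, fixed here because a total
order is needed for determinism -- and every fifth record is held out.
One subtlety of the rule is worth knowing when designing simulations:
if every cow contributes exactly five records (or a multiple of five),
the every-fifth positions align with the within-cow position, and since
days sort ascending within cow, the hold-out then consists solely of
each cow's latest-day -- hence lactation -- record. Real recording
schemes have varying record counts, which breaks the alignment; the
generator's defaults (7 records per cow) avoid it too.

`validate_model()` evaluates predictions separately per period (a
record's own period is used, never re-derived from the prediction) and
reports RMSPE, $R^2$, and the decomposition of the mean square
prediction error

$$\mathrm{MSPE} = \underbrace{(\bar O - \bar P)^2}_{\mathrm{ECT}}
 + \underbrace{(s_P - r\,s_O)^2}_{\mathrm{ER}}
 + \underbrace{(1 - r^2)\,s_O^2}_{\mathrm{ED}},$$

the error of central tendency (systematic level shift), the error due to
regression (observed-on-predicted slope away from 1) and the error due
to disturbance (irreducible scatter). Population (divide-by-$n$)
standard deviations are used inside the decomposition so the three-term
identity is exact to machine precision; $R^2$ uses the ordinary sample
correlation. The centered-residual regression of $O - P$ on
$P - \bar P$ summarizes the same information as an intercept (= mean
bias) and slope (= $\mathrm{cov}(O,P)/\mathrm{var}(P) - 1$); both
closed-form identities are asserted in the test suite. Component
percentages are reported to 3 decimals.

## The synthetic-herd generator

Because the original Austrian records are not public, the package
carries a seeded generator, `simulate_herd()`, that emulates their
printed structure and makes the whole pipeline testable:

* **Population structure.** 167 farms, roughly 38 cows per farm and 7
  weighings per cow by default; genotype mixture proportional to the
  reported 2604/773/373/1056/1500 cows per class; RH gene fractions
  uniform within each Fleckvieh subclass's interval (informational only
  -- the class label drives the model); parities from a truncated
  geometric distribution on 1--13 calibrated to a mean of 3.0; 10 % of
  records in the dry period (the reported ratio of dry to lactating
  validation records).
* **Measurements.** Per record, the eleven traits are drawn from a
  period-specific truncated multivariate normal whose means, SDs and
  bounds come from the published descriptive tables and whose
  correlation matrix is the published period-specific correlation table.
  Assembled correlation targets are checked for positive
  semi-definiteness and, if needed, projected to the nearest PSD
  correlation matrix (`repair_correlation()`; the default matrices are
  already PSD, so no entry is altered). Truncation is by rejection at
  the record level with a capped number of redraw rounds, so infeasible
  bounds fail fast instead of looping.
* **Weights.** `bw = predict_bw(record, truth) + farm effect +
  residual`, with the packaged `hgbghw` equation as default truth, farm
  effects $N(0, 20^2)$ kg and residuals $N(0, 30.4^2)$ kg (32.5 kg when
  the `hgbg` equation generates). The residual SDs are the published
  model RMSEs of the respective equations; the farm-effect SD is not
  published and 20 kg is the package's choice of a plausible
  between-herd spread -- parameter-recovery results are insensitive to
  it. Realized farm effects and residuals are stored with each record,
  so the generating identity is reconstructable exactly.

What the generator does **not** emulate: within-cow correlation between
repeated weighings beyond the shared farm effect, trajectories of
measurements along lactation (belly girth in particular rises through
lactation in real data; an explicit day trend is not modelled),
breed-by-measurement mean differences, and missing-value patterns.
Passing tests on synthetic herds therefore demonstrate the correctness
of the estimation and validation machinery under the declared generating
model -- not the field accuracy of re-fitted equations on real herds.

### Stage-day modes and the noiseless limit

By default stage days are drawn uniformly over each period's domain,
which leaves within-stage-class curve variation in the residual (worth a
few tenths of a kg of apparent RMSE). For exactness studies,
`stage_days = "midpoint"` places records at class midpoint days so the
categorical stage model holds exactly in the generator; combined with a
vanishing residual SD (e.g. `1e-8`; the configuration requires a
strictly positive value) and `farm_sd = 0`, a re-fit returns every
identifiable generating coefficient to below $10^{-6}$.

## Numerical choices

* Stage polynomials are evaluated directly from their coefficients;
  13-point degree-4 fits at the midpoint days are well conditioned (the
  test suite confirms recovery of an exact polynomial to $10^{-8}$).
* The REML optimizer runs with derivative checks disabled for speed; a
  non-zero optimizer code is raised as an error, never silently
  accepted.
* Zero-variance predictions make ER/ED undefined; the decomposition
  refuses them explicitly. A validation period with fewer than 3 records
  is flagged `insufficient` instead of failing the run.
* Serialization (coefficient sets as YAML, records as tab-separated
  text) writes numbers with enough significant digits that read-back is
  bit-exact; every pipeline artifact is listed in a manifest with its
  content hash and the seed.

## Problem sizes used in the shipped checks

The test suite and the acceptance script work at sizes chosen to make
sampling error small relative to the assertions while staying quick:
structural tests use herds of 90--1200 records, moment-recovery checks
about 11 000, and parameter-recovery and hold-out validation checks
about 20 000 records (167 farms x 17 cows x 7 weighings), the scale at
which the pooled heart-girth slope is estimated with a standard error of
roughly 0.07 kg/cm. Disturbance-share checks average 10 seeded
replicates because the dry-period hold-out (~400 records) gives the ECT
and ER shares long-tailed single-replicate distributions.

## Known limitations

* The packaged equations apply to the breeds, measurement protocol and
  weight range they were derived from; extrapolation to other breeds or
  to heifers is unsupported.
* Predictions are population-level; per-farm calibration (adding a farm
  BLUP) is not implemented.
* The equations require the exact measurements of their `model_spec`;
  no imputation of missing girths is attempted.
* BCS- or linear-trait-only equations are intentionally not packaged:
  they predict weight too poorly to be useful substitutes for girth
  measurements.
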