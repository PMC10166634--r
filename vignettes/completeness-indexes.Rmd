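---
title: "Completeness indexes for complete cancer prevalence: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Completeness indexes for complete cancer prevalence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(prevcomplete)
```

## The estimation problem

Registries observe prevalence only over their registration period.
Writing `N_d` for the number of persons alive at the index date and
diagnosed within the past `d` years, and `C` for complete prevalence,
the completeness index `R_d = N_d / C` converts one into the other:
`C = N_d / R_d`, and more generally
`N_{d2} = N_{d1} / (R_{d1} / R_{d2})` extends observed prevalence to any
longer duration. The package estimates `R` three ways — model-based,
empirical, and externally supplied — on a common cell structure
(sex, site, age group at the prevalence date, annual duration).

## Conventions

* **Durations** are completed whole years, measured from the diagnosis
  date to the day before the index date, so a registry opening 1 January
  of year `Y0` with index date 1 January of year `Y` yields strata
  `0 .. Y - Y0 - 1`, and `N_d` sums strata `0 .. d-1`. A patient
  diagnosed on the index date is not prevalent.
* **Ages** follow a start-of-year bookkeeping: the age attained at a
  1 January index date is `age at diagnosis + duration + 1`. This is the
  unique convention consistent with the model convolution below, in
  which a person aged `a` at the index with duration `t` was diagnosed
  at age `a - t - 1`. (Under the alternative "age at diagnosis plus
  completed years" reading, the convolution and a direct enumeration of
  the same cohort disagree by one year of age, which visibly biases
  grouped indexes wherever `R` changes steeply with age.)
* Two age-grouping schemes: `model_5y_85plus` (5-year groups, 85+) for
  modelled quantities, and `empirical_wide` (0-29, 5-year, 80+) where
  observed counts at extreme ages are too sparse.

## The counting method

Limited-duration prevalence is enumerated at the index date: patients
known alive count 1, known dead count 0, and patients lost to follow-up
contribute the probability of being alive — the product of annual
conditional survival probabilities of their own patient cohort from the
year after loss to the index date. Cohort survival is actuarial
(losses and administrative censorings half-exposed), stratified by sex,
site, age band at diagnosis (0-59, 60-74, 75+) and 5-year period of
diagnosis. Sparse strata fall back deterministically: drop the period,
then the age band, then pool sites (sex is never pooled). No cap is
applied to the weighting horizon. With no losses the method reproduces a
brute-force enumeration exactly; this is asserted in the tests.

## Model-based R-indexes

### Relative survival and the cure model

Ederer II cohort relative survival is computed on annual intervals:
observed actuarial survival divided by expected survival, where the
expected interval factor is the mean general-population annual survival
probability (matched on sex, attained age, calendar year) over patients
at risk at the interval start. A Weibull mixture cure model

`RS(t) = c + (1 - c) exp(-(lambda t)^gamma)`

is fitted to the cumulative RS points by weighted least squares
(weights inverse to the Greenwood-based variance of RS), with bounds
`c in [0, 1]`, `gamma in (0.05, 10)`, `lambda in (1e-4, 10)` and a
multistart grid `c in {0.1, 0.5, 0.9} x gamma in {0.5, 1, 2} x
lambda in {0.1, 0.5, 1}`; the best converged start wins and
non-convergence is flagged, never silently accepted. Survival strata
default to the same 0-59/60-74/75+ bands used for loss to follow-up; a
pooled all-ages fit is kept as a deterministic fallback for bands too
sparse to support their own curve.

### Incidence

Incidence is tabulated by 5-year age group (85+) and 5-year period of
diagnosis, with person-year denominators from the population table, and
modelled by binomial logistic regression: a parametric age term plus
nonparametric 10-year birth-cohort indicators (reference = earliest
cohort; cohorts outside the fitted range use the nearest estimated
effect, which the lifelong lookback requires). The age variable is the
group midpoint centred at 50 and scaled by 50 before polynomial
expansion — degree-6 terms on a [-1, 1] variable stay well conditioned.
"Exponential" age dependence is read as a single linear age term on the
logit scale; the degree-6 polynomial is the flexible alternative, and
AIC (`-2 loglik + 2k`, ties to fewer parameters) arbitrates. On
early-onset or bimodal age profiles the polynomial wins decisively; the
tests assert this as a property.

### The convolution

For a single age `a` at the index date, the modelled prevalent mass
within `d` years is

`P(a, d) = sum_{t=0}^{min(d, a - a_min) - 1} I(a-t-1, cohort(a)) * RS(t + 1/2)`

and `R(a, d) = P(a, d) / P(a, D_max)` with lifelong lookback
`D_max = a - a_min` (`a_min` = the site's minimum diagnosis age).
Survival is evaluated at interval midpoints; the midpoint rule bounds
the discretisation bias of the yearly grid.

**Why expected survival does not appear.** Within the birth cohort
currently aged `a`, the probability of having been diagnosed `t` years
ago and being alive now is proportional to
`l(a-t-1) * I * RS(t) * S*(t)`: cohort survivorship to the diagnosis
age, incidence, and patient survival `RS * S*`. Since
`l(a-t-1) * S*(t) = l(a)` for every `t`, both factors cancel from the
ratio, leaving `I * RS`. Multiplying by `S*` *without* the
survivorship-weighted population at risk double-counts other-cause
mortality and biases `R` upward at old ages (we measured up to +0.10 at
ages 80-84 against the simulation oracle before adopting this form).
The count-based variant (`use_expected_survival = TRUE`) is retained for
completeness but is only meaningful together with explicit historical
population weights.

**Grouping.** Five-year (or empirical-wide) group values are ratios of
population-weighted prevalent masses,
`R_g(d) = sum_a w_a P(a,d) / sum_a w_a P(a,D_max)`, with weights from
the population table at the index year. A population-weighted mean of
single-age `R` values was rejected: in wide heterogeneous groups (the
0-29 group of an early-onset site) ages whose lookback horizon is
shorter than `d` contribute `R = 1` regardless of their negligible
prevalent mass, inflating the group value and even flipping the sign of
empirical-vs-model comparisons at short registration lengths. The
mass-weighted ratio is the aggregation consistent with dividing grouped
counts by the index.

Computed `R` is clipped to 1 only within numerical noise (1e-9); larger
excursions raise an error rather than masking a defect.

## Empirical and external indexes

The empirical index is `R_{i,d} = N_{i,<=d} / N_{i,<=35}` from a
long-series registry pool, on the wide age grouping; it assumes 35-year
observed prevalence is essentially complete. Cells with a zero
long-series denominator are emitted as missing with a warning. External
index tables load from the same CSV schema
(`sex,site,age_group,duration,R,method`), are validated for the (0, 1]
range (error) and monotonicity in duration (warning listing cells), and
are interchangeable with internally computed indexes downstream.

## Validation statistics

* `APRD = sum_r (|N'_r - N_r| / N_r) w_r * 100`, weights = each
  registry's share of observed prevalent cases, normalised; absolute
  values prevent compensation. Used in the truncation experiment:
  truncate observed prevalence to `d1 in {5, 10, 15}` years, extend to
  20 via `R_{d1} / R_{20}`, compare with observed 20-year prevalence.
* `PRD = sum_r ((N_alt,r - N_std,r) / N_std,r) w_r * 100`, signed,
  weights = resident population; negative values mean the alternative
  method underestimates the standard. Summarised by registration-length
  group (10-14, 15-19, 20-24, 25-35 years).

## The simulator's stated world

The microsimulator generates what the estimators assume, so that a green
test isolates estimator defects from model misspecification:

* yearly grid, uniform within-year event timing; incident counts are
  binomial draws per (sex, age, year) cell;
* cause-specific death times from the band-wise mixture cure model,
  other-cause death times from the life table, independent competing
  risks (the independence assumption of relative survival);
* loss to follow-up as independent exponential censoring, default
  hazard 0.001/year, keeping the lost proportion under the 2% typical
  of real registries;
* a Gompertz-Makeham life table (constant over calendar time, male
  mortality 35% higher), and a population age structure **stationary
  under that life table** (weights proportional to survivorship
  `l(a)`) — the demographically self-consistent choice; the R-index
  itself is population-structure-free, since the structure cancels
  within birth cohorts;
* four shipped contrast scenarios: `pancreas_like` (late onset, low
  survival), `breast_like` (late onset, high survival), `testis_like`
  (early onset, high survival; quadratic logit age profile) and
  `bimodal_like` (quartic, peaks near 30 and 70). The first two are
  log-linear in age so the exponential incidence model is exactly
  well-specified; all polynomial profiles are nested in the degree-6
  fitting basis. Cohort effects default to a mild +0.02 logit per
  decade;
* the `age_step5` option makes the true age profile piecewise constant
  on the 5-year fitting grid; parameter-recovery experiments use it so
  that "recovered within 2 SE" is a statement about the estimator, not
  about binning bias (at large n the 5-year binning bias of a smooth
  profile exceeds the coefficient standard errors).

What the simulator does **not** emulate: calendar-period effects in
incidence, screening waves, survival improvement over time (a crude
per-period multiplier hook exists but defaults off), migration,
non-stationary populations, registry-specific data quality. A green
test therefore establishes correctness of the estimation chain under the
method's own assumptions, not robustness to their violation.

## Numerical and design choices

* Dates at day resolution; all strata annual.
* The acceptance property "model R within 0.02 of the
  simulation oracle at 1e5 cases" is evaluated with ages 40-84 pooled
  per duration: per-5-year-cell truth ratios at that sample size carry
  Monte-Carlo standard errors of 0.01-0.13 (cell prevalent pools range
  from ~10 to ~1000), so a 0.02 cell-level band is unattainable for any
  unbiased estimator; we verified across seeds that per-cell deviations
  flip sign. Pooling is the statement the stated world can support, and
  the package meets it with margin (observed deviations ~0.005).
* Pipeline configs are JSON (no YAML parser is assumed available);
  a single master seed fans out to per-stage substreams (derived
  modulo 2^31), making `run-all` byte-reproducible — asserted by
  hashing every artifact across two runs.
* Unknown vital status other than explicit "lost" is not modelled; any
  non-dead, non-confirmed-alive record is treated as lost.

## Known limitations

* Confidence intervals for R-indexes (and hence for complete prevalence)
  are not provided; the reference methodology does not define them for
  empirical indexes and interval estimation was excluded rather than
  guessed.
* The cure model is Weibull-only (no flexible or non-mixture cure
  models), matching the standard tooling's restriction.
* Fallback pooling for sparse survival strata is deterministic but
  crude; with very sparse sites the pooled all-ages curve dominates.
* The empirical index inherits the finite-horizon bias it is known for:
  for early-onset sites even 35 years of observation miss long-term
  survivors, and the package reproduces (and quantifies, via PRD) the
  resulting systematic underestimation rather than correcting it.
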