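---
title: "Methods: synthetic registers, exposure proxy, phenotyping and inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic registers, exposure proxy, phenotyping and inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pfascohort)
```

This vignette documents the models and procedures implemented in
`pfascohort`, the parameters that matter, the design decisions taken where
the design was genuinely open, and what the synthetic-data tests do and do
not establish about real register data.

## 1. The study design being emulated

The package implements a register-based open cohort of all children born
over an 8-year window in a county containing a localized drinking-water
PFAS point source. Children enter at birth and are followed until outcome
incidence, death, emigration, an outcome-specific age cap (3rd birthday
for wheeze, 12th for the asthma outcomes) or the administrative end of
study. Prenatal exposure is a four-level proxy computed from the mother's
addresses in the five calendar years preceding the delivery year; outcomes
are phenotyped from specialist-care diagnoses (ICD-10) and pharmacy
dispensations (ATC); confounding is addressed with covariate-adjusted Cox
models and, in a secondary potential-outcomes analysis, with matching plus
Fisherian randomization inference.

## 2. The synthetic register generator

`generate_registers()` produces linked tables (births, maternal
address-years, diagnoses, dispensations, vital events, parental event
streams, serum biomarkers) with the statistical structure the analysis
assumes. It is first-class, tested code: every invariant the pipeline
relies on (schema, determinism, classifier round-trip, phenotyper
contract) is asserted in the test suite.

### Latent outcome model

Latent onset ages follow a piecewise-constant hazard on age with knots at
36 months and 6 years (per-day weights 1 : 0.45 : 0.18). This matches the
qualitative shape of childhood asthma incidence — steeply front-loaded,
flattening after school age — without over-parameterization. The child's
hazard is multiplied by `exp(log HR_group + γ'Z + frailty)`, where the
default covariate log-hazard shifts are smoking 0.26, parental asthma
0.69, male sex 0.30, foreign-born parent 0.10 — moderate, literature-sized
effects chosen once so that confounding adjustment is non-trivial. The
scale of the baseline hazard is calibrated by `uniroot` so that the
*background group's* latent cumulative incidence by the age cap equals
`baseline_cuminc` (defaults 0.18 for wheeze by 36 months and 0.17 for
asthma by age 12, the study-population prevalences). Because the wheeze
stream also receives the early (< 36 months) asthma onsets, the
wheeze-specific process is calibrated net of the early-asthma
contribution, so the *total* background wheeze incidence hits its target.

A fraction `persist_prob` (default 0.76 ≈ 13/17) of early-onset asthma
cases also emits a qualifying event after 36 months and therefore meets
the stricter asthma (3+) definition.

### Event emission and the generator/phenotyper contract

An onset observable before censoring emits either a J45 diagnosis at the
onset day (probability 0.4) or a first R03 dispensation at onset plus a
confirming repeat; the repeat is placed before the censoring time, and
for early-onset cases that are *not* persistent it is placed before the
3rd birthday so that no spurious post-36-month event exists. Noise events
are constructed never to satisfy any algorithm: isolated unrepeated
dispensations after 36 months (non-cases only), respiratory-infection
diagnoses after 36 months, and extra infant infections only for children
who are already wheeze cases. Consequently phenotyping recovers the
latent labels *exactly*, with or without noise — a deliberate contract
that turns the phenotyping algorithms into a testable boundary rather
than an approximation. Real register data, of course, contain coding
errors and care-seeking variation that this contract excludes; the
separate sensitivity/specificity machinery (`confusion_metrics()`)
exists precisely to quantify that gap against a configurable gold
standard.

### Population structure

Sibling pairs are realized within exposure groups at `sibling_rate`
(default 0.24 of children sharing a mother), with 1–3 calendar years
between births. Covariate distributions default to the per-group margins
of the baseline-characteristics table (e.g., maternal smoking
7.2/8.3/17.1/9.8% across background/intermediate/high/very-high);
covariates are drawn conditionally independent given the group, which is
sufficient for testing confounding adjustment though it understates
real-world covariate correlation. Parental asthma is a family-level
trait; affected parents receive event streams that satisfy the asthma
algorithm, so the parental indicator is itself phenotyped, not copied.
Missingness defaults to MCAR at rates (smoking 6%, education 2%, income
1.5%) that jointly leave ≈ 91% of children covariate-complete; an MAR
option tilts missingness toward low-income families for imputation
stress-testing. Within-family outcome correlation beyond shared
covariates is off by default (`frailty_sd = 0`): the analysis model uses
cluster-robust variance rather than a frailty term, and a shared-frailty
default would change the marginal meaning of the calibrated incidences;
the parameter exists for sensitivity analyses.

Address histories are constructed to be *exactly* classifiable: very-high
mothers hold contaminated addresses for every window year of every
delivery, high mothers for exactly one (the year before the first
delivery, which lies inside every sibling's window because birth gaps are
at most 3 years), intermediate mothers live in Ronneby on the clean
waterworks, background mothers outside Ronneby. The classifier round-trip
is tested at 100%.

### Biomarker cohort

Serum PFOS/PFHxS/PFOA are lognormal per exposure group with medians set
to the validation-cohort table and log-scale spreads derived from the
printed interquartile ratios (`sdlog = log(q3/q1)/(2·Φ⁻¹(0.75))`). With
`sdlog = 0` the distribution collapses to the median exactly (used as a
degenerate-input test).

## 3. Exposure classification

`classify_prenatal_exposure()` applies the window rule
[delivery−5, delivery−1]. Window years without an address record are
treated as "not in Ronneby" *provided at least one window year is
recorded*; a fully empty window raises an error instead of silently
assigning background, because the background definition requires
registration in the county. Duplicate records within a year resolve by
logical OR on the contamination flag (exposure-maximizing). Both
decisions are deliberate: silent defaults hide data problems, and the OR
rule can only misclassify *upward*, which is rare and conservative for
the contrast of interest. Classification is order-invariant, ignores
records outside the window, and is monotone in added contaminated years
(property-tested).

## 4. Outcome phenotyping

The three algorithms are implemented over code-set prefixes
(`code_set_config()`): asthma ICD J45; wheeze ICD J45 + J20–J22; ATC R03
for both. Decisions:

* R03 (the whole obstructive-airway-disease chapter) is the default
  dispensation set and is configurable rather than hard-coded, since the
  canonical Swedish code list is maintained outside this package.
* `repeat_window_days` defaults to unlimited — any second dispensation
  confirms — because the validated algorithm requires only "at least one
  repeated dispensation". Both dispensations must fall before the age-12
  cap.
* 36 months and age 12 are operationalized as the 3rd and 12th birthdays;
  an event *on* the birthday counts as after it. A Feb-29 birthday rolls
  to Mar 1 in non-leap years.
* The asthma incident date is the first qualifying diagnosis or *first*
  dispensation (the repeat confirms retroactively); asthma (3+) keeps the
  same incident date (lookahead confirmation by the post-36-month event).

These yield the tested invariants: asthma (3+) ⊆ asthma with identical
incident ages, and adding events can only create cases or move incidence
earlier.

## 5. Follow-up and covariates

Exit is the minimum of incident age, death, emigration, cap and
administrative end, with same-day ties resolved event > death >
emigration > cap > admin end, so incidence on a censoring boundary counts
as an event (consistent with the incidence algorithm's semantics).
The administrative-end exit counts the final study day as lived
(`admin_end − birth + 1` days). Children who emigrate are censored
permanently at first emigration. Income and maternal-age quartiles are
empirical quartiles of the analysis cohort; degenerate distributions
trigger a warning and a single level. Complete-case analysis removes any
child with a missing covariate and reports per-covariate missingness plus
an included/excluded comparison.

## 6. Survival models

`cox_fit()` wraps `survival::coxph` with the model specification fixed by
the package contract: age (days) as the time axis, baseline stratified by
sex × parity (adjusted model) or sex alone (simple model), exposure as
three indicator contrasts against background, Efron tie handling
(day-resolution ages make ties common), and a sandwich variance
aggregated over maternal sibling clusters. The simple model contains no
covariates besides exposure — the most literal reading of a
"simple model" — and the adjusted model adds smoking, education,
foreign-born parent, parental asthma, income quartiles and maternal-age
quartiles. Oracle tests verify the coefficients against direct
partial-likelihood maximization on small untied fixtures, the score test
against an independent log-rank statistic, and the cluster-size-1
sandwich against the unclustered robust variance.

Proportional hazards are assessed two ways: per-covariate scaled
Schoenfeld residuals against Kaplan–Meier-transformed time
(`survival::cox.zph`), and a joint cluster-robust Wald test of
exposure-by-time interactions from a time-split refit (`survSplit` at
event-time deciles). The KM transform is evaluated at the episode
*start*, making it a step-function time-varying coefficient that is
constant within each risk set; the background-level interaction column is
then risk-set-constant, carries no partial-likelihood information, and is
dropped as aliased, leaving a 3-df test of the exposure-specific time
trends. (Evaluating the transform at each row's own end time would make
the event subject's value always extreme in its risk set and drive the
fit to a monotone likelihood — a pitfall the implementation avoids by
construction.) Sex-modification is tested by a joint robust Wald on the
exposure×sex terms (the sex main effect is absorbed by the stratified
baseline; one interaction column is stratum-collinear and aliased), with
per-sex refits reported alongside.

## 7. Multiple imputation and pooling

The chained-equations core uses the conventional fully-conditional
methods: Bayesian logistic draws for binary smoking, multinomial draws
for 3-level education, and type-1 predictive mean matching (5 donors) for
continuous income. Every conditional model includes the other covariates,
exposure, sex, parity, the outcome-specific event indicator and the
Nelson–Aalen cumulative-hazard value at the subject's own exit — the
standard survival-compatible predictor set. Defaults are m = 20 datasets
× 20 sweeps; tests use smaller m for speed, and the no-missing-data path
returns identical copies. Pooling follows Rubin's rules on the log-HR
scale (normality holds there), T = W̄ + (1 + 1/m)B, with the standard
small-sample degrees of freedom and exponentiation afterward.
Income/age quartiles are recomputed within each completed dataset.

## 8. Matched randomization inference

The secondary analysis operationalizes the potential-outcomes framework:

* **Distance.** Covariates are replaced by pooled midranks; the rank
  covariance has its diagonal rescaled to the untied-rank variance
  (N²−1)/12 (the robust variant, preventing heavily tied binary
  covariates from dominating); squared Mahalanobis distances are computed
  under that matrix, with ridge regularization and a warning if it is
  singular. Rank-invariance to monotone transforms is tested.
* **Matching.** Greedy 3:1 nearest-neighbour without replacement, treated
  units in input order, ties broken by control input index —
  deterministic by construction, and the order convention is stated here
  because different reference implementations disagree.
* **Statistic.** T = KM cumulative incidence (treated) − (control) at the
  last observed time at or before the outcome age cap, in percentage
  points. The cap (rather than the maximum observed time) is the default
  horizon because it is the estimand's natural endpoint and does not
  drift with the censoring pattern; it is a parameter.
* **Test.** Under the sharp null, one member of each matched set of four
  is relabeled treated, uniformly and independently — the unique scheme
  preserving the 1:3 design — and T is recomputed with follow-up records
  traveling with the child. p = (1 + #{T* ≥ T_obs}) / (1 + n_perm)
  one-sided (excess incidence among treated), never zero by
  construction; with ≤ 8 sets the full 4^S distribution is enumerated
  and the exact proportion is reported instead. The permutation kernel
  is an O(n) tabulation over a pre-sorted tie-group structure, so 10⁵
  permutations over a ~800-child matched cohort take seconds.

Balance is reported as standardized mean differences with the
pre-matching pooled SD as denominator before *and* after matching, so the
two columns share a scale.

## 9. Validation statistics

The Jonckheere–Terpstra statistic sums between-group Mann–Whitney counts
over ordered group pairs with half credit for ties. For total n ≤ 10 the
null distribution is enumerated exactly over all distinct group
assignments (the enumeration count is the multinomial coefficient; a
guard falls back to the tie-corrected normal approximation if it exceeds
2·10⁵); otherwise the tie-corrected normal approximation is used, with a
zero-variance guard returning p = 1 for degenerate data. The exact/
approximate threshold is a package choice — the variant used in the
original analyses is not documented — and both paths are cross-checked
against a brute-force double loop and Monte-Carlo permutation.
Sensitivity/specificity are plain confusion-table ratios with undefined-
metric flags for empty classes; the gold standard is a configurable rule
in the same phenotyping engine, since primary-care gold-standard
definitions live outside the package.

## 10. Problem sizes, tolerances and limitations

The test suite runs the full pipeline at cohort sizes 250–6,000 and the
simulation studies at the sizes a desk machine handles comfortably:
parameter recovery uses 200 cohorts of 10,000 children (mean log-HR
compared to log 1.5 within 3 Monte-Carlo standard errors; robust-CI
coverage required in [92%, 98%]), the randomization-test null calibration
uses 500 replicates of 40 matched sets with 399 permutations each, and
the proportional-hazards Wald calibration uses 200 cohorts of 3,000
(rejection within the 99% binomial band around 5%; smaller cohorts leave
too few very-high events for the 3-df asymptotics). Randomization
p-values are conservative in the presence of ties in the statistic's
null atoms, which is intrinsic to the test, not an implementation
artifact.

What passing tests show: the pipeline's estimators are correct against
independent oracles, its tests are calibrated under their nulls, and the
generator meets its own calibration targets. What they do not show: that
real register data satisfy the generator's assumptions — exact
phenotyping, conditionally independent covariates, MCAR missingness,
permanent addresses between snapshots — nor anything about the magnitude
of real-world exposure effects. The package's claims are about the
machinery, not about epidemiology.
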