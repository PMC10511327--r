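---
title: "Classifying wasting episodes and pooling longitudinal growth statistics"
author: "wastingepi"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying wasting episodes and pooling longitudinal growth statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wastingepi)
```

## The problem

Child wasting — a weight-for-length z-score (WLZ) below −2 against the WHO
2006 growth standard — is an acute, episodic condition. Cross-sectional
surveys measure its *point prevalence*, but a child can enter and leave the
wasted state several times before age two, so prevalence badly understates
the share of children who ever experience wasting. Quantifying that burden
requires longitudinal cohorts measured at least monthly and a reproducible
rule for turning each child's noisy WLZ series into discrete episodes with
onsets, recoveries, durations, and person-time at risk. `wastingepi`
implements that rule and the surrounding statistical machinery:
age-stratified summaries, two-stage random-effects pooling across cohorts,
rainfall-seasonality contrasts, and a regression-to-the-mean (RTM)
correction — together with a synthetic cohort generator with known ground
truth, because the multi-cohort data this style of analysis is designed for
are typically access-controlled.

## The episode model

All analysis runs on integer ages in days; month-denominated parameters are
converted with `DAYS_PER_MONTH = 30.4167`.

A child's non-missing WLZ measurements define a latent wasted/non-wasted
step function that switches halfway between consecutive measurements of
opposite status:

* **Onset** is the midpoint between the last measurement at or above the
  cutoff and the first below it. Children already wasted at their first
  measurement are handled by enrollment type: a *birth measure* (first
  retained measurement at age ≤ 7 days) gives an `at_birth` onset at that
  age; a later first measurement gives an `at_enrollment` onset halfway
  between birth and that measurement.
* **Recovery** is the midpoint between the last measurement below the
  cutoff and the first at or above it — *provided the child stays above the
  cutoff for at least the washout period* (default 60 days; 30- and 90-day
  sensitivity variants). An above-cutoff spell shorter than the washout is
  a blip inside the same episode, not a recovery, so episode counts are
  monotone non-increasing in the washout length.
* A trailing above-cutoff spell that is never contradicted before
  observation ends is accepted as a recovery. This is a deliberate design
  choice: demanding a fully observed 60-day run would reclassify the
  canonical worked example — not wasted at 40 d, wasted at 70 d, not wasted
  at 100 d with a confirming visit at 130 d, one episode of
  (70−40)/2 + (100−70)/2 = 30 days — as censored, which is not how the
  episode schematic treats it. The stricter reading is available as
  `recovery_rule = "two_measurements"`, which additionally requires the
  above-cutoff run to contain two confirming measurements.
* A child still below the cutoff at the last measurement carries a
  **censored** episode, ended administratively at the last measurement age,
  with no duration.

Severe-wasting episodes use the same machinery at cutoff −3. Missing-WLZ
visits are skipped and midpoints bracket the nearest non-missing
neighbours; no maximum-gap rule is applied, but gaps over 90 days are
logged.

```{r worked-example}
m <- generate_fixture(data.frame(
  child_id = "k1", age_days = c(40, 70, 100, 130),
  wlz = c(-1.5, -2.5, -1.5, -1.5)))
classify_episodes(m, analysis_config())[, c("onset_age_days",
  "recovery_age_days", "duration_days", "censored")]
```

The classifier is verified, measurement-list against day-grid, by an
independent brute-force oracle that replays the threshold and washout rules
literally on a half-day grid; the test suite requires exact agreement of
onsets, recoveries, censoring and durations on 1,000 randomly generated
series for every combination of washout (30/60/90) and cutoff (−2/−3).

### Person-time and rates

A child contributes person-time at risk from the start of observation,
minus `[onset, recovery + washout)` for every episode (censored episodes
remove time through the series end). At-risk plus not-at-risk days equal
the observed span *exactly* — a conservation property the tests enforce to
zero tolerance. The incidence rate is onsets per 1,000 at-risk child-days
in an age window, with an exact Poisson interval on the onset count;
`exclude_onset_kinds` reproduces the sensitivity analysis that drops
episodes present at birth or enrollment.

### Recovery and duration

Recovery proportions at 30/60/90 days count uncensored episodes with
duration at or below the horizon. The default denominator keeps episodes
that either recovered within the horizon or were observed at least that
long after onset, so administratively censored episodes with short
follow-up do not deflate recovery (`denominator = "all"` is available; the
choice is documented rather than prescribed by the field). Under either
rule the proportions are non-decreasing in the horizon. The median duration
is reported only where fewer than half of a cohort's episodes are censored;
medians are pooled across cohorts by the unweighted median of medians.

## Cross-sectional and cumulative summaries

* **Point prevalence** at an age stratum uses every child with a qualifying
  measurement within ±1 month of the target age; a child is prevalent if
  *any* visit in the window meets the condition (wasting WLZ < −2, severe
  WLZ < −3, stunting LAZ < −2, underweight WAZ < −2, concurrent
  wasting–stunting both at the same visit). Averaging across a child's
  in-window visits would be the obvious alternative; the any-visit rule is
  deterministic and is applied uniformly.
* **Cumulative incidence** counts children with at least one onset by the
  target age, over children observed by that age; it is non-decreasing in
  age while prevalence need not be.
* **Incidence proportion** over a window excludes children wasted (or in
  washout) at the window start from numerator and denominator alike.
* **Persistent wasting**: at least 50% of a child's WLZ measurements below
  −2, among children with ≥ 4 measurements. The boundary is inclusive by
  default with a `persistent_strict` switch, because the two natural
  readings ("50% or more" vs "greater than 50%") genuinely differ at, say,
  3 wasted visits out of 6.
* The **faltering partition** assigns each child at a stratum to one of
  eight mutually exclusive categories from current status and history;
  children currently wasted *and* stunted are classified
  `wasted_stunted_underweight` (such children are underweight as a matter
  of growth-standard arithmetic, and the synthetic generator preserves the
  implication by construction). Proportions are rescaled to sum to one.

## Two-stage pooling

Cohort-level estimates are pooled with `metafor::rma()`: random effects by
REML (DerSimonian–Laird on non-convergence) or fixed-effects
inverse-variance weighting, with heterogeneity reported as
I² = max(0, (Q − df)/Q) × 100. Proportions are pooled on the logit scale
with delta-method standard errors and back-transformed; the raw scale is
available by flag, and boundary proportions are nudged by half an event
(requiring the denominator) so their logit stays finite. A single cohort
passes through flagged rather than pretending to be a meta-analysis. The
identity between fixed-effects pooling and the inverse-variance mean, and
REML's recovery of a known between-cohort variance (τ² = 0.04), are tested
against closed forms and simulation rather than against the library
itself. The nominal-coverage property of the random-effects interval is
checked at 20 cohorts, where its asymptotics are adequate; with very few
cohorts Wald intervals undercover, which is a known limitation, not a bug.

## Rainfall seasonality

The seasonality index is `(1/R) Σ |Xₙ − R/12|` over study-period mean
monthly rainfall totals, bounded by 0 (uniform) and 11/6 (all rain in one
month), scale-invariant, with classes high (≥ 0.9), medium (0.7–0.9), low
(< 0.7). The peak-rain window is the three consecutive months (wrapping
December–January) with the highest mean rainfall, ties broken to the
earliest calendar start. WLZ is contrasted across four quarters anchored on
that window (peak, pre-peak, post-peak, opposite-as-reference) by an
ordinary linear model on quarter indicators, deliberately unadjusted:
seasonal forcing is treated as exogenous. Measurements are assigned to
quarters by the calendar month of the visit; a boundary date belongs to the
month it falls in, hence to the earlier quarter. Files without dates are
accepted by the readers but refused by the seasonality stages with a clear
error.

## Regression to the mean

Children selected for being below a threshold at baseline will, on
average, look better at follow-up even with no true catch-up. The package
uses the classical linear RTM expectation under bivariate normality:
`E[follow-up | selected] = μ + r (selected mean − μ)`, with the RTM effect
`(1 − r)(μ − selected mean)`. The population mean μ is the cohort mean at
the baseline stratum, and the correlation r is estimated from *all* paired
children, not only the selected group, which would bias it. The formula
assumes a stationary mean across the lag; the self-consistency test
therefore runs on a generator configuration with a flat age curve, and the
production helper reports expected and observed follow-up means
side-by-side so age drift is visible rather than silently absorbed.

## The synthetic cohort generator

`simulate_cohorts()` draws monthly series from birth (or late enrollment)
to 24 months as

```
z = agecurve(age) + season(month) + birthmonth_offset + child_intercept + AR1
```

with defaults chosen once as a realistic monthly-anthropometry regime: a
piecewise-linear WLZ age curve from −0.5 at birth rising slightly before
declining to about −1.0 at 12 months; child random-intercept SD 0.5;
AR(1) residuals (coefficient 0.5 — monthly z-scores are serially
correlated) with marginal SDs 0.76 (WLZ) and 0.64 (LAZ), the
within-child variability scale typical of such cohorts; a sinusoidal
seasonal term with amplitude 0.2 z and trough in the peak-rainfall month,
evaluated on the discrete calendar month so quarter-mean contrasts have an
exact closed form; geometric attrition at 2% per month; and 2,000 children
per cohort in the parameter-recovery tests (500 by default). WAZ is the
blend `0.55·WLZ + 0.55·LAZ + ε` with ε truncated to ±0.2 (SD 0.15): the
truncation turns "wasted and stunted implies underweight" into a hard
invariant, which unbounded noise cannot provide. The truth table records
per-visit statuses by thresholding the emitted z-scores — exact agreement
with the measurements is itself a tested invariant — plus the dropout age.

What the generator does *not* emulate: measurement-error heaping and
digit preference, missing WLZ for neonates under 45 cm, mortality and
treatment referral, country-level covariates, and gestational-age
corrections. Tests passing on synthetic data therefore certify the
*pipeline arithmetic* — classification, person-time accounting, pooling —
under the stated stochastic model, not the epidemiology of any real
population.

### Numerical choices and degenerate inputs

* Boundary QC values (WLZ exactly ±5, LAZ ±6, WAZ −6/5) are retained; the
  exclusions are strict inequalities. The filter is idempotent and
  conserves counts per indicator.
* Duplicate same-age rows keep the first parsed record; the rest are
  flagged, never silently dropped.
* An above-cutoff spell counts as sustained at exactly the washout length
  (≥, not >); the day-grid oracle encodes the same convention, so the
  equivalence test would catch a drift in either.
* Zero at-risk time, empty denominators, empty quarters and all-censored
  cohorts return explicit `undefined` flags rather than NaN arithmetic.
* Episode classification is deterministic; the only randomness anywhere is
  in the generator and in simulation-based tests, all seeded.

### Problem sizes used by the test suite

Oracle equivalence and person-time conservation run on 1,000 random series
(≤ 30 visits) for each washout/cutoff combination; parameter recovery uses
3 cohorts × 2,000 children; REML recovery uses 500 simulated meta-analyses
of 5 cohorts; coverage uses 600 replicates of 20 cohorts; RTM simulation
uses 4,000–5,000 children. These sizes keep Monte-Carlo standard errors
small enough that the 3-SE acceptance bands are meaningful.

## Known limitations

Recovery is treated as spontaneous (no treatment-referral model) and there
is no competing-risk correction for mortality. The length-decrease
technical-error screen runs only when raw lengths are supplied, with a
configurable allowance (1 cm default) because no standard threshold
exists. WLZ computation from raw weight and length is out of scope — the
engine consumes z-scores, and an adapter would sit upstream of
`read_measurements()`.
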