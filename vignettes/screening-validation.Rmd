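---
title: "Validating short alcohol screens against the last-four-occasions method"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating short alcohol screens against the last-four-occasions method}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grogscreen)
```

## The measurement model

Screening for risky drinking in populations with intermittent,
heavy-per-occasion drinking runs into two problems at once: the notion of
a *usual* drinking frequency may not describe anyone's behaviour, and
converting shared, non-standard containers into standard drinks is hard to
do in one's head. The last-four-occasions (Finnish) approach sidesteps
both by asking concretely about the four most recent drinking days — when
each occurred, and what was drunk, container by container.

The package implements that assessment and the instruments validated
against it.

**Consumption arithmetic.** A beverage entry contributes
`volume × ABV × fullness × share × count × 0.789` grams of ethanol
(0.789 g/mL is the density of ethanol; the survey instrument performs this
conversion internally, so the constant is fixed here as the standard
reference value), and 10 g of ethanol is one Australian standard drink.
Fractional counts and shares are equivalent routes to the same quantity —
`count = 0.5` and `share = 0.5` commute — which the tests assert.

**Finnish-method estimators.** With occasions ordered most recent first
and `d_i` the days back to occasion `i`:

- frequency (occasions/month): `k_f / max(d_{k_f}, 1) × 30.4375`,
- usual quantity (drinks/occasion): mean of the `k_q` most recent
  quantities,
- average consumption (drinks/day): their product divided by 30.4375,
- maximum single occasion: the largest recorded quantity.

The source analyses state the estimators' outputs (occasions per month,
drinks per occasion, average drinks per day) but not the frequency
formula itself. The `k/span` renewal-style estimator used here is the
natural reading: it treats the time back to the k-th occasion as `k`
renewal intervals, keeps shortened (`k < 4`) and full variants directly
comparable, and collapses to the obvious answer for evenly spaced
histories. The span is clamped to one day so a same-day occasion does not
divide by zero; with `k_q = k_f = 4` the average reduces to (total drinks
over the four occasions) / (days back to the fourth), an identity asserted
to 1e-12 in the tests. Occasions more than 366 days back fall outside the
"past 12 months" recall window and are dropped before computation;
a person left with no in-window occasion is treated as a past-year
non-drinker. Ties in `days_before_survey` are legitimate (two recorded
occasions on one day) and keep their file order.

**AUDIT-Cm.** The three consumption items of AUDIT-C in colloquial
wording. AUDIT-1m (frequency) and AUDIT-3mV (frequency of 5+ drink days)
score their ordinal category 0–4; AUDIT-1m offers no "never" because only
past-year drinkers are asked. AUDIT-2m is *derived*: the continuous usual
quantity is recoded into the printed categories (1–2 → 0, 3–4 → 1, 5–6 →
2, 7–9 → 3, 10+ → 4). The printed categories are integer drink counts, so
a continuous estimate falling in a gap (4.5 drinks) is rounded half-up to
an integer first; half-up rather than banker's rounding because the
categories are read as counts, and the choice only affects values exactly
halfway. The total (0–12) flags risk at ≥ 3 for women and ≥ 4 for men.

**Midpoint risk estimators.** The item subsets classify risk through
category midpoints. The midpoint table (per day) is: never 0;
less-than-monthly 0.5/30.4375; 1–3 times a month 2/30.4375; a few times a
week 2/7; most days 5.5/7. Only one anchor is fixed by the source
analysis — weekly drinking is 1/7 ≈ 0.14/day — and the labels themselves
are inconsistent between items (the weekly category reads "2–3 times a
week" on one item and "1–3 times a week" on another); 2/week is used for
both, and the whole table is a `pipeline_config()` parameter so
sensitivity to these choices is directly testable. Quantity midpoints are
1.5, 3.5, 5.5, 8 and, for the unbounded top category, 10 standard drinks.
AUDIT-1m+2m flags short-term risk when the quantity midpoint exceeds 4
drinks and the person drank in the past year (a stricter at-least-monthly
gate is available as `short_term_min_frequency = "monthly"`, since the
source tables describe the monthly variant while the methods text
describes past-year); long-term risk when midpoint frequency × midpoint
quantity exceeds 2/day. AUDIT-3mV alone: any non-never response is
short-term risk; long-term risk multiplies 5 drinks by the midpoint
frequency. A consequence of the default midpoints worth knowing: AUDIT-3mV
long-term risk is *equivalent* to answering "most days" (5 × 5.5/7 ≈ 3.93
is the only product above 2), which the tests assert across all five
categories.

**Concordance.** Sensitivity `tp/(tp+fn)` and specificity `tn/(fp+tn)`
against the Finnish reference, with exact Clopper–Pearson 95% intervals
from beta quantiles. The exact family is used because it reproduces the
published worked-example intervals from their 2×2 counts (e.g. 6/9 →
29.9–92.5); it is conservative, with realised coverage at least nominal —
a property the suite checks by simulation. The published 2×2 itself is
recovered by `two_by_two_from_margins()`: total, reference-positive,
index-positive and disagreement counts determine all four cells uniquely.

**Shortening.** `retention_grid()` computes, for each `(k_q, k_f)` in
1..4 × 1..4, every drinker's shortened average-drinks-per-day estimate and
its squared Pearson correlation with the full (4, 4) estimate — the
proportion of variance retained. Average drinks/day is the default
correlated variable because it is the one quantity that combines both axes
of the grid; the quantity component alone (`drinks_per_occasion`) is
available behind a config switch since the source never names the
correlated variable explicitly. Drinkers with fewer than four in-window
occasions are excluded from this analysis only (and counted); the
diagonal entry (4, 4) is exactly 1 by construction. A sensitivity variant
drops drinkers whose four quantities are all equal (tolerance 1e-9 drinks)
to rule out trivial retention from copied answers.

## The synthetic cohort

The participant-level study data cannot be released, so the generator in
`cohort_params()` / `generate_cohort()` emulates the study conditions the
analyses assume. Its defaults are the conditions, not tuning knobs:

- **Stratification**: 200 participants, 20% past-year non-drinkers, and
  half of drinkers in the "dependent" stratum (any endorsed ICD-11
  dependence symptom) — mirroring a recruitment design of 20 non-drinkers
  and 40 + 40 non-dependent/dependent drinkers per site. Dependence is
  sampling metadata only; it never enters risk computation.
- **Frequency**: each drinker's latent occasion rate is uniform within
  their frequency class, classes distributed 30.4 / 42.4 / 26.1 / 1.1
  percent (rare / 1–3 per month / weekly / most days) — the emulated
  response margins. Occasions follow an exponential renewal process
  backwards from a stationary, window-truncated first offset; an optional
  on/off burstiness flag (default off) makes gaps alternate between triple
  and one-third rate for users who want heavier clustering, at the cost of
  analysability.
- **Quantity**: log-normal per occasion with median 17 standard drinks
  (the emulated cohort's reported median is 16–18), decomposed into a
  between-person spread of usual quantity (`sigma_between = 0.62`) and a
  smaller within-person spread (`sigma_within = 0.30`), plus a 7% minority
  of genuinely light drinkers centred on 2.5 drinks. The mixture is not
  ornamental: a single log-normal at median 17 cannot simultaneously put
  ~78% of drinkers in the 10+ usual-quantity category and leave ~5% who
  never exceed 4 drinks on a recorded occasion — the heavy tail forces
  nearly everyone over the short-term threshold. The spreads were fixed
  analytically against the usual-quantity category margins
  (`P(mean-of-4 ≥ 9.5)` under the mixture) before any downstream result
  was inspected, and are stated here as the package's definition of the
  emulated population.
- **Self-report**: the true AUDIT-1m category bins the latent rate at
  1/month, 1/week and 3.5/week; the true AUDIT-3mV category is "never"
  when no recorded in-window occasion exceeded 4 drinks and otherwise bins
  the latent heavy-occasion rate (rate × P(quantity > 4)) with
  less-than-monthly as floor. With `noise_prob > 0` a report moves to an
  adjacent category (exactly one step; at a boundary the only legal step
  is taken). `copy_prob` lets earlier occasions copy the most recent
  occasion's quantity, emulating a questionnaire shortcut of unknown
  prevalence — hence default 0.
- The survey records only the four most recent occasions;
  `generate_occasions()` exposes the full in-window latent history, and
  the cohort truncates it to four, which is also why "maximum on any
  single drinking day" is an under-estimate of the true any-day maximum —
  for the recorded data and the generator alike.

What the generator does *not* emulate: seasonal or community-level dry
periods, correlation between drinking pattern and sex or dependence
stratum, autocorrelated occasion spacing, and digit preference or other
structured misreporting. Consequences are visible and expected: simulated
retention grids are more pessimistic in the frequency dimension than a
real cohort's, because i.i.d. exponential gaps make the time back to the
first occasion a noisy frequency estimate, whereas real four-occasion
histories are smoother and partly copied. Passing calibration checks
therefore demonstrate internal consistency of the pipeline under the
stated model, not agreement with any real population.

## Numerical and design choices

- Ethanol density 0.789 g/mL; 10 g per standard drink; 30.4375 days/month
  (365.25/12); 366-day recall window. All exposed as package constants.
- Strict inequalities at the NHMRC thresholds: exactly 2 drinks/day or
  exactly 4 drinks on the worst day is *not* at risk.
- ABV is a percentage in files and a fraction in memory; the conversion
  happens only in `read_products()`.
- CSV schemas are exact (header, UTF-8, '.' decimals); unknown tokens are
  rejected with the offending file, line and expected-token list, and
  referential integrity (every occasion's `person_id` present in the
  responses) is checked before analysis.
- All randomness flows from a single integer seed in `cohort_params()`;
  regeneration is byte-identical.
- Problem sizes used by the shipped analyses: the workflow scripts run the
  200-person default cohort; the calibration checks in the test-suite use
  a 5000-drinker cohort, large enough that the multinomial margins pin the
  emulated percentages to a fraction of a point.

## Limitations

The pipeline inherits the reference method's circularity: AUDIT-2m is
derived from the same last-four-occasions data that defines the reference
classification, so AUDIT-2m-based comparisons are optimistic relative to
an independently administered quantity item. The frequency estimator is a
documented design choice, not a reconstruction of the original
instrument's internal formula. And the synthetic cohort is a stand-in with
the stated structure — results on it validate the code and the method's
internal behaviour, not field performance.
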