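# grogscreen

Validation analyses for short alcohol-screening tools against the
last-four-occasions ("Finnish") method of consumption assessment.

## The problem

In populations where drinking is intermittent but heavy per occasion —
as reported for many Aboriginal and Torres Strait Islander communities —
standard screening items that presume a *usual* drinking pattern can
misbehave. One alternative asks in detail about the **last four drinking
occasions**: when each occurred and how much was consumed, with quantities
built up from real containers (product, container volume, fullness, the
share of a shared pour) rather than abstract "standard drinks". From those
four occasions the Finnish method derives:

- drinking frequency: `f = k / max(d_k, 1) × 30.4375` occasions/month,
  where `d_k` is the number of days back to the k-th most recent occasion
  (k ≤ 4);
- usual quantity: `q = mean(drinks on the k most recent occasions)`;
- average consumption: `q × f / 30.4375` standard drinks/day
  (1 Australian standard drink = 10 g ethanol);
- the maximum single-occasion quantity.

Risk is classified under the 2009 Australian NHMRC guidelines: **long-term
risk** if average consumption exceeds 2 standard drinks/day, **short-term
risk** if more than 4 standard drinks were consumed on any recorded
drinking day (both strict inequalities).

The package evaluates how well shorter instruments recover that reference
classification:

- **AUDIT-Cm** — a colloquially worded AUDIT-C: a frequency item
  (AUDIT-1m), a quantity item derived by recoding the Finnish usual
  quantity into the AUDIT-2 categories (AUDIT-2m: 1–2 → 0, 3–4 → 1,
  5–6 → 2, 7–9 → 3, 10+ → 4), and a visually presented 5+-drinks frequency
  item (AUDIT-3mV). At-risk: total ≥ 3 (women) or ≥ 4 (men).
- **AUDIT-1m + AUDIT-2m** and **AUDIT-3mV alone** — category-midpoint risk
  estimators (e.g. once-weekly drinking = 1/7 ≈ 0.14 occasions/day;
  the open-ended 10+ category is assigned 10 drinks).
- **Shortened Finnish variants** — using only the last 1–3 occasions for
  the quantity and/or frequency component, scored by r², the proportion of
  variance in average drinks/day retained relative to the full method.

Concordance is summarised by sensitivity and specificity with exact
(Clopper–Pearson) 95% confidence intervals. Because the underlying survey
data cannot be shared, the package includes a seeded synthetic-cohort
generator with the same statistical structure (stratified sampling,
exponential-renewal occasion timing, log-normal heavy quantities, ordinal
self-report with optional noise), so the whole pipeline is reproducible
and testable.

## Worked example

The analysis workflow lives in `analysis/` (simulate → score → concordance
→ shortening), writing its tables under `results/`. In miniature:

```r
library(grogscreen)

# the published worked example: the AUDIT-Cm vs Finnish 2x2 reconstructed
# from its marginals (184 drinkers, 175 reference-positive,
# 177 index-positive, 4 disagreements)
tab <- two_by_two_from_margins(184, 175, 177, 4)
str(tab)
#> List of 4
#>  $ tp: num 174
#>  $ fn: num 1
#>  $ fp: num 3
#>  $ tn: num 6
r <- sensitivity_specificity(tab)
round(100 * c(r$sensitivity, r$ci_sensitivity), 1)
#>         lower upper
#>  99.4   96.9 100.0
round(100 * c(r$specificity, r$ci_specificity), 1)
#>        lower upper
#>  66.7   29.9  92.5
```

So the AUDIT-Cm catches 174 of the 175 drinkers the Finnish method flags
(sensitivity 99%), while 3 of the 9 reference-negative drinkers are
flagged anyway (specificity 67%, with the wide exact interval a margin of
9 implies). A full simulated run:

```r
simulate_cohort_files(cohort_params(seed = 42), "cohort")
out <- run_pipeline("cohort", output_dir = "cohort_results")
out$log$n_analysed          # drinkers analysed
round(100 * out$retention$grid, 1)  # variance retained by shortened variants
```

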