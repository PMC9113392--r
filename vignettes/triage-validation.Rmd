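---
title: "Validating a five-level pediatric triage rule against PEWS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating a five-level pediatric triage rule against PEWS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pedtriage)
```

## The problem

Emergency-department triage assigns every arriving child an ordinal
acuity level — here a five-level scale where level 1 is a
life-threatening emergency to be seen immediately and level 5 a
non-urgent consultation that can safely wait four hours. Levels 1–2 are
called *high-level emergencies*, levels 3–5 *low-level*. Because no
ground truth exists for "how sick is this child really", a triage rule
is validated as a diagnostic test against a reference standard; the
reference used here is the Pediatric Early Warning Score (PEWS), a
0–9 sum of three 0–3 component ratings (behavior, cardiovascular,
respiratory), dichotomized at the conventional cutoff of 4/9.

`pedtriage` implements both instruments and the full validation
pipeline: the triage rule engine, the PEWS scorer, the 2×5
cross-tabulation and its dichotomized diagnostic statistics, stratified
subgroup reports, outcome and length-of-stay analyses, and a synthetic
cohort generator whose defaults encode a published 100,506-visit
validation cohort so every stage can be exercised end to end.

## The triage decision rule

The rule mirrors nurse-led triage workflow as a chain of four steps,
each of which can only *increase* severity (numerically lower the
level):

1. **Critical shortcut.** A child failing the ABCDE primary survey
   stops triage immediately at level 1 (`critical_flag`). Level 1 is
   the only level compatible with "triage stops so that lifesaving care
   starts", which is why the shortcut maps there rather than to level 2.
2. **Item aggregation.** Otherwise the nurse selects every applicable
   chief-complaint item; each item carries a base level, and the most
   severe selected item (the minimum) is the suggested level
   (`aggregate_items()`).
3. **Risk overrides.** Conditions like *newborn* (matched automatically
   from age < 28 days) or *immunosuppressed* force the level to at most
   their assigned level, 2 by default (`apply_risk_overrides()`).
4. **Vital-sign moderation.** Any measured vital sign outside its
   age-band reference range escalates to at most the range's configured
   escalation level (`moderate_by_vitals()`). Vital signs that were
   *not entered* are treated as normal — the same convention the
   validation data used — so absence is a first-class `NA`, never a 0.

A nurse may afterwards upgrade the level (`nurse_override()`), never
downgrade; a downgrade request is refused with a classed warning and
leaves the result untouched. Each final level maps to a fractile
response-time target of 0/15/60/120/240 minutes.

```{r}
cfg <- default_triage_config()
p <- presentation(age_days = 10, sex = "male",
                  selected_items = "limb trauma, no deformity")
evaluate_triage(p, cfg)
```

The clinical content of real triage item lists is proprietary, so the
default configuration is deliberately synthetic: a complete grid of one
item per complaint category and level (labelled `"<category>/L<level>"`)
plus a few readable aliases, plausible but invented age-banded vital
ranges, and escalation always to level 2. It exercises every rule
pathway while making no claim to clinical fidelity; real deployments
supply their own YAML/JSON configuration (`read_triage_config()`).

## Diagnostic validity statistics

`build_crosstab()` tallies the 2×5 table of reference acuity by triage
level; `dichotomize()` pools it into TP/FP/FN/TN with levels 1–2 as
test-positive. `diagnostic_summary()` then reports, with 95% intervals:

* sensitivity, specificity, PPV, NPV — exact binomial
  (Clopper–Pearson) intervals. The exact method is the default because
  it reproduces the reference cohort's printed bounds at one-decimal
  rounding at every statistic; the Wilson score interval, which differs
  in the third significant figure, is available via
  `proportion_ci(method = "wilson")`.
* LR+ = sens/(1−spec) and LR− = (1−sens)/spec — log-method intervals
  (`exp(ln LR ± z·SE)` with the usual two-proportion variance).
* agreement, over-triage (FP/n) and under-triage (FN/n), which
  partition the cohort exactly.

The printed counts of the reference cohort's agreement table prove that
its over/under-triage definition is the dichotomized one (over-triage
15,082 = 135 + 14,947 is exactly the FP pool); an ordinal variant that
also counts within-class discrepancies is available behind
`over_under_counts(scale = "ordinal")` but is off by default.

Any statistic with a zero denominator is `NA`, never 0 — report
renderers emit the literal `"NA"` — matching how sparse subgroups are
reported in practice. Subgroup analyses (`stratified_validity()`)
recompute the whole panel within strata of sex, age band, complaint
type/category or diagnosis; per-stratum confusions pool exactly to the
cohort confusion, which the tests assert.

```{r}
ct <- reference_crosstab()
diagnostic_summary(dichotomize(ct))
```

## Severity-outcome analyses

`outcome_rates_by_level()` reports ICU/hospitalization/transfer/
discharge proportions per level with exact binomial intervals.
`los_anova()` compares length of stay across levels with a one-way
fixed-effects ANOVA computed from the between/within sum-of-squares
decomposition — implemented directly so the decomposition is available
to callers, and cross-checked in the tests against
`stats::oneway.test(var.equal = TRUE)` to 1e-10 — followed by Scheffé
simultaneous pairwise contrasts at the study-wide α of 0.001 (a
conservative level appropriate to a six-figure cohort; the companion
`bonferroni_threshold()` divides it across declared comparison
families). Scheffé was chosen because it controls the family-wise error
over *all* contrasts, not just the tested pairs, and needs no
balanced-design assumption; levels with fewer than two observations are
dropped with a warning.

## The synthetic cohort

`default_cohort_params()` encodes the reference validation cohort:
level marginal (217 / 16,575 / 34,832 / 41,302 / 7,580 of 100,506),
P(PEWS high | level) from the agreement-table cells (82/217 …
1/7,580), and per-level sex, age-band, complaint-category, outcome,
diagnosis and LOS parameters from its descriptive tables. Percentages
are as printed (one decimal) and renormalized to exact probability
vectors. `generate_cohort()` samples level-first, then every other
attribute conditionally on level.

Choices worth knowing about:

* **Conditional independence.** Joint distributions (e.g. age ×
  complaint within a level) were never published, so attributes are
  independent given the level. This is a stated simplification of the
  generator, not a claim about the real cohort.
* **LOS model.** Only mean ± SD per level is known; LOS is drawn from a
  normal truncated at zero. Truncation shifts the realized moments
  slightly (≈ +4 min on the mean at level 4); tests compare against the
  analytic truncated-normal moments, not the raw parameters.
* **PEWS totals.** No total-score distribution was published, so given
  the intended acuity the total is uniform on {4..9} (high) or {0..3}
  (low), then split uniformly over the valid 0–3 compositions into the
  three components.
* **Round-trip construction.** Each visit's item set is built so its
  max-severity aggregation equals the intended level (half of level-1
  visits use the critical shortcut instead), vitals are absent or
  in-range, and no risk conditions are flagged — so re-triaging the
  cohort reproduces the intended levels exactly, which is asserted at
  100%. One interaction needs care: the engine automatically caps
  newborns at the newborn assigned level, so visits drawn at levels 3–5
  resample their age band among the older bands. This distorts the age
  marginal by under 0.3 percentage points.
* **Reproducibility.** Every attribute has its own fixed-consumption
  uniform stream derived from the seed, so `generate_cohort(n + m,
  seed)` extends `generate_cohort(n, seed)` without reshuffling.

What passing the recovery tests shows — and does not show: running the
full pipeline on 200,000 generated visits recovers the parameter-implied
sensitivity (76.4%), specificity (84.7%) and agreement within binomial
error, demonstrating that the engine, scorer and metrics compose without
bias. It does not validate the triage rule clinically: the synthetic
items are placeholders, PEWS component splits are uninformative, and
real missingness, measurement error and case-mix correlation structure
are absent.

## Problem sizes and numerical conventions

The test suite runs its recovery check at n = 200,000 (the reference
cohort's order of magnitude halved, with binomial-SE tolerances) and
property suites at a few hundred to a few thousand cases each; the full
suite completes in a couple of minutes on one core. Other conventions:
age bands are half-open (`[0, 28)` days, …) with one month = 30.44 days
and one year = 365.25 days; all internal computation is full precision
with rounding (one decimal for percentages and LRs) applied only in the
report layer; infinite likelihood ratios are kept internally but render
as `"NA"`; ties in item aggregation need no tie-break because the
minimum is well-defined.

## Limitations

Real per-stratum subgroup counts of the reference cohort were never
published, so stratified results cannot be checked against printed
values and are covered by pooling/NA-semantics properties instead. The
2018–19 second-period cohort is likewise out of reach (its parameters
can be supplied as an alternative `cohort_params()`). The PEWS rubric
bands shipped are a Monaghan-style stand-in; only the component
integers matter to the validation pipeline.
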