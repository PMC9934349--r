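---
title: "Phenotyping SLE in observational data: algorithms, simulation and bias analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phenotyping SLE in observational data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(SlePhenotyper)
```

## The algorithms

A phenotype algorithm translates "has SLE" into executable rules over
coded events. Four cohort definitions are built from three orthogonal
rules, each a pure function of one person's event history:

* **First diagnosis code.** The anchor is the earliest event whose
  `(vocabulary, code)` lies in the SLE diagnosis concept set (SNOMED
  257628, ICD-10-CM M32.9, ICD-9-CM 710.0 in the shipped default;
  production code lists are supplied via `load_concept_sets()`).
  Matching is exact string match — no vocabulary hierarchy expansion —
  because algorithm code lists enumerate literal codes.
* **Confirmation (`*_2x`).** A second diagnosis code 31–365 days
  *after the first code*. Both endpoints are inclusive: the definitions
  are written as closed ranges, so day 31 and day 365 qualify and day
  30 does not. The window is anchored at the first code, not the
  corrected index; the confirmatory code confirms the diagnosis, not
  the prodrome.
* **Index-date correction.** Entry is re-anchored to the earliest SLE
  sign/symptom or treatment-drug event 1–90 days before the first
  code. Drugs participate on equal footing with signs and symptoms.
  There is no chaining: an event 95 days out never qualifies by way of
  a nearer event. Ninety days is the window in the published
  definitions; precursor rates fall off sharply before that horizon.
* **Washout (`incident_*`).** At least 365 days of observation before
  the index date — evaluated at the *corrected* index, since the
  corrected date is the claimed disease start. A prodrome that pulls
  the index to day 350 of observation therefore removes the person
  from the incident cohorts while leaving prevalent entry intact.

A person enters each cohort at most once, at the first qualifying
episode; exit/re-entry logic is out of scope. Ties (several entry
events on the same day) are broken deterministically: signs/symptoms
before drugs, then vocabulary, then code — so cohorts are independent
of event ordering.

Two comparator algorithms ("3X + antimalarial", with and without
exclusion of dermatomyositis and systemic sclerosis) require three
diagnosis codes on *distinct calendar dates* and ever-use of an
antimalarial. Distinct dates are an interpretation choice — the
published description does not say whether duplicate same-day billing
rows count — and guard against them; the index is the later of the
third distinct-date code and the first antimalarial, uncorrected.

## The simulator

Real validation data for these algorithms are proprietary claims and
EHR databases; the simulator (`simulate_population()`) provides a
synthetic stand-in with known ground truth so every downstream
component is testable. It emulates the structural features the
algorithms key on; its distributional forms are stand-ins, not fitted
models.

Per person it draws: one observation period (length exponential,
median `followup_years_median = 1.5` years, placed inside the calendar
window so the window end does not truncate the length distribution);
sex and an age uniform on 0–84; latent SLE with hazard
`sle_incidence_per_100k_py = 16` scaled by a female:male multiplier of
7 (≈87% female cases at a balanced population) and 10-year age-band
multipliers decaying geometrically from the `50-59` peak, normalised
so the population marginal onset rate matches the configured
incidence. Onset precedes observation start with probability
`prevalent_case_fraction = 0.3`, else is uniform within observation.

Cases receive a first diagnosis code at onset plus a geometric delay
(mean 45 days, clamped into observation), repeat codes by a monthly
Bernoulli (`repeat_code_prob_per_month = 0.25`), and
hydroxychloroquine with probability 0.38. Non-cases receive at most
one spurious rule-out SLE code (probability 0.002) that never repeats
and never co-occurs with an antimalarial — precisely the false-positive
mechanism the confirmed-code and comparator rules exploit, documented
so users can stress it. Everyone accrues background sign/symptom
events as a Poisson process (0.3/person-year) and comorbidity codes
per an enrichment map (defaults: rheumatoid arthritis 12%/2%
case/non-case, renal impairment 8%/1.5%, heart disease 10%/4%).

Two deliberate calibrations:

* **Prodrome probability is an observable target.** Background
  symptoms land in the 90-day pre-diagnosis window with probability
  `1 − exp(−0.3·90/365.25) ≈ 7.1%`, so inserting prodromes with raw
  probability `prodrome_prob` would push the precursor share of index
  events above the configured value. The insertion probability is
  deflated to `(p − p_bg)/(1 − p_bg)` so that the *realised* fraction
  of case index events anchored on a precursor targets `prodrome_prob
  = 0.45`, matching the reported 40–50% share.
* **Prodrome drugs are corticosteroids only** (prednisone,
  methylprednisolone). Hydroxychloroquine is modelled separately after
  the first code, so "ever antimalarial" in the comparator algorithms
  is governed by one parameter rather than leaking in through
  prodromes.

All draws come from a single seeded generator in documented order:
periods, demographics, latent status, per-case coding (in person
order), non-case rule-outs, non-case antimalarials, background events,
comorbidities, visit context. A fixed seed reproduces the database
byte for byte.

What the simulator does **not** reproduce: multiple observation
periods per person, realistic visit/billing structure, laboratory
results (ANA testing is not part of these algorithms), code-hierarchy
noise, or between-database heterogeneity. Passing property tests on
synthetic data therefore shows the algorithms implement their rules
and respond to the modelled mechanisms — it does not certify
performance on any real database.

## Evaluation

Ground-truth evaluation is person-level with no index-date tolerance:
the algorithm claims case status, and timing accuracy is reported
separately by `index_date_error()` (signed, absolute and exact-match
summaries of index minus onset). The denominator excludes true cases
whose onset falls outside their observation period; for them no coded
record of the onset episode can exist, and with ~30% prevalent cases
the choice materially affects sensitivity, so it is worth stating
prominently: prevalent cohort entries of such cases are not counted
either way.

Confidence intervals are Wilson score intervals, computed in closed
form and cross-checked against `prop.test(correct = FALSE)`; they
remain stable at the extreme specificities (≥0.997) these algorithms
produce. F1 is reported without an interval — it is not a single
binomial proportion. Cross-database summaries are unweighted means of
point estimates, rounded to whole percents for reporting, which
reproduces the published summary figures; recomputing on pooled counts
would weight large databases and is deliberately not done.

## Diagnostics

`incidence_rate()` starts at-risk time 365 days into observation
(aligning denominators with the incident washout), censors at cohort
entry, and can stratify by sex, 10-year age band and calendar year
with person-time split across years. `smd_binary()` computes
`(p1 − p2)/sqrt(p1(1−p1) + p2(1−p2))`: the published two-decimal
cohort-comparison values reproduce exactly under this denominator and
not under the textbook pooled form with `/2`, which is available via
`pooled = TRUE`. `match_controls()` samples up to 10 unique non-case
controls per case matched on sex, 5-year age band and the year-month
of the case's index (the control's index becomes their first event in
that month), requiring 365 days of prior observation; 5-year bands
keep 1:10 matching feasible at simulation scale. A magnitude above 0.1
conventionally flags imbalance.

## Quantitative bias analysis

The corrective equations take the algorithm's sensitivity and
specificity as parameters. The package adopts the Rogan–Gladen
estimator — the standard form for outcome misclassification with known
(Se, Sp) — for both prevalence and incidence, flooring/clipping to the
valid range and refusing non-informative classifiers (Se + Sp ≤ 1).
Uncertainty is propagated by drawing (Se, Sp) from Beta distributions
moment-matched to each point estimate and its 95% CI (draws stay in
[0, 1] and are seeded); non-informative draws are discarded, and an
error is raised if more than half are lost. Zero-width CIs collapse to
the deterministic correction.

## Problem sizes and numerical choices in the test suite

The tests exercise the code at sizes chosen to make each check
statistically meaningful on one CPU: brute-force oracle agreement on
200 random databases of ≤20 persons; direction-of-effect (PPV up,
sensitivity down with confirmation; sensitivity lower with washout) on
one 100,000-person default simulation; the precursor-share check on
100,000 persons with incidence raised to 2,000/100k PY, because at the
realistic default of 16/100k PY a desk-scale cohort holds only tens of
cases and a ±3-percentage-point check would be noise; the matching
check on 150,000 persons over a 4-year window with 6 background
events/person-year, approximating claims visit density so 1:10 pools
exist. Recovery of true prevalence by the correction uses 100
synthetic-misclassification replicates plus 20 end-to-end pipeline
replicates at 30,000 persons. Elevating incidence or event density in
a property test changes only the Monte-Carlo resolution of that test,
never the parameter under test.

## Limitations

The algorithms are faithful implementations of published rules, but
the performance numbers shipped with the package come from proprietary
databases and cannot be recomputed here; the simulator demonstrates
mechanisms, not magnitudes. Single-code incident cohorts cannot
distinguish rule-out coding from true disease — visible here as low
simulated PPV for `*_1x`. The default concept sets are the compact
main-text subset; production use requires complete code lists via
configuration.
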