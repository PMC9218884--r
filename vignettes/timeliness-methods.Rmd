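---
title: "Backtesting warning timeliness and false-positive outcomes for asthma hospital-visit risk models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Backtesting warning timeliness and false-positive outcomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asthmawarn)
```

## The problem

Health systems use annual risk models to decide which asthma patients to
enrol in care-management programs: a model scores every asthma patient at
the end of an index year, the highest-scoring decile is flagged, and flagged
patients are considered for preventive intervention against asthma hospital
visits (emergency-department visits or inpatient stays with a principal
asthma diagnosis) in the following 12 months.

Two questions about such a model are not answered by its ROC curve:

1. **Timeliness.** For a patient who *does* go on to have a hospital visit,
   how many days before the visit would the model first have raised a
   warning, had it been consulted daily?
2. **False-positive quality.** For a patient flagged by the model who has
   *no* home-system hospital visit in the outcome window, how often does the
   patient nevertheless show a poor outcome — a systemic-corticosteroid
   course, an exacerbation-coded visit, a hospital visit at an outside
   facility, or a hospital visit one further year out?

`asthmawarn` implements both analyses as a tested pipeline and supplies a
synthetic longitudinal EHR cohort generator so every stage can be exercised,
and its statistical machinery verified, without access to protected health
records.

## The advance-warning statistic k

Let $T$ be the starting date of the patient's first asthma hospital visit in
the evaluation year. Starting from $T-365$ and moving forward one day at a
time, let $T'$ be the earliest date ($T-365 \le T' \le T-1$) on which the
model — given only the patient's history up to $T'$ — predicts a future
asthma hospital visit. The model then warned the patient's first asthma
hospital visit after $T'$

$$k = (\text{first asthma hospital visit after } T') - T', \qquad 1 \le k \le T - T',$$

days in advance. If no scan date is predicted positive, $k = 0$: the model
warned only on the day of the visit itself. Two subtleties are implemented
literally:

* The visit that defines $k$ is the first one *after* $T'$, which may be an
  earlier visit than $T$ (for example a prior-year visit that falls inside
  the scan window).
* Predictions on dates after $T'$ are irrelevant; only the earliest positive
  matters.

The distribution of $k$ over event patients is summarised by its mean and
SD, by a *warning survival curve* (the number of patients with $k \ge c$ for
$c = 0,\dots,365$), and by counts at the reporting horizons 12/6/3/1 months,
2 weeks and 1 day, mapped to 365/180/90/30/14/1 days. The month-to-day
mapping is configurable via the `thresholds` argument of
`summarize_leadtimes()`.

**Threshold during the scan.** Classification uses the *frozen* top-decile
threshold obtained from the test cohort's end-of-year scores
(`apply_cutoff()` then `set_frozen_threshold()`). Recomputing a decile
cutoff at every scan date would require the whole cohort's scores on that
date — including patients' data that, mid-year, would be future data for the
annual instance construction — so freezing is the only choice that needs no
information beyond the annual classification itself. This is an
interpretation: the statistic's definition fixes the model but is silent on
mid-year cutoffs.

## Cohort and visit definitions

* **Case-finding:** a patient has asthma in a calendar year if at least one
  visit billing record of that year carries an asthma diagnosis code (ICD-10
  `J45.x`, ICD-9 `493.0x/493.1x/493.8x/493.9x`), and the patient did not die
  that year. Matching is prefix-based on dot-stripped codes
  (`code_rules()`), so `"J45909"` and `"J45.909"` are equivalent.
* **Asthma hospital visit:** an ED visit or inpatient stay — home or
  external — whose *principal* diagnosis is asthma. A secondary asthma code
  does not qualify.
* **Exacerbation visit:** any visit type whose principal diagnosis is in a
  configurable exacerbation code set. No standard enumeration of
  "asthma-exacerbation" codes exists for this analysis, so the default
  covers the ICD "with (acute) exacerbation" and status-asthmaticus families
  (`J45.21/31/41/51/901/902`, `493.02/12/92`) and is explicitly a documented,
  configurable choice.
* **"Primary or principal" diagnosis** is modelled as the single
  `principal_code` field on each visit row.

## Annual instances and the risk model

For each index year, one instance is built per qualifying patient: an as-of
date anchored at 31 December, features from history up to the as-of date,
and a label equal to "at least one *home-system* asthma hospital visit in
the half-open window (as-of, as-of + 365]". Home-system restriction mirrors
a model trained on a single system's warehouse, which cannot observe outside
visits — that blindness is precisely what the false-positive analysis
quantifies.

Features follow a compact, configurable specification (`feature_spec()`):
utilization counts (ED, inpatient, outpatient, asthma-coded visits,
corticosteroid orders) over trailing 90/180/365-day windows,
days-since-last recency features, and optionally age and sex. Windows are
half-open, `(as_of - w, as_of]`, so an event exactly at the as-of date
counts and an event exactly `w` days earlier does not. `days_since_last`
uses the sentinel `w + 1` when no event falls in the window, keeping the
feature bounded and monotone. Real deployed models use much richer feature
sets; this panel is a stand-in that preserves the structure the analyses
need (temporal hygiene, recency, burstiness). Temporal hygiene is enforced
by construction — features are computed from sorted per-category date
vectors with `findInterval`, so post-as-of events cannot leak — and checked
by mutation tests.

The classifier is pluggable: gradient boosting (`xgboost`, single-threaded
and seeded, hence deterministic) by default, logistic regression as a
cross-check engine, and a fixed linear scorer (`linear_risk_model()`) for
experiments that need a closed-form scoring rule.

**Top-decile cutoff.** `apply_cutoff()` flags exactly
$\lfloor 0.10\,N\rfloor$ patients (14,644 patients would yield 1464), with
ties broken by ascending patient id for reproducibility; the threshold is
the lowest flagged score.

## False-positive surrogate indicators

For each flagged patient without a home-system asthma hospital visit in the
outcome window, four indicators are evaluated from windows anchored at the
same as-of date:

| indicator | window | definition |
|---|---|---|
| 1 | (as-of, +365] | ≥1 systemic-corticosteroid order |
| 2 | (as-of, +365] | ≥1 visit (any type) with exacerbation principal diagnosis |
| 3 | (+365, +730] | ≥1 asthma hospital visit |
| 4 | (as-of, +365] | ≥1 *external* asthma hospital visit |

plus the corticosteroid *multiplicity* — every order in the 12-month window
counted, so indicator 1 is equivalent to multiplicity ≥ 1. Indicators 1-3
are evaluated on home-system records (indicator 3 optionally on any source
via `ind3_home_only = FALSE`; the home-only default matches indicators
computed from a single system's warehouse, while indicator 4 exists exactly
to look outside it). When the months-13-24 window extends past the data
span, indicator 3 is reported `FALSE` with `ind3_evaluable = FALSE` and a
warning rather than silently guessed. Day-anchored windows coincide with
calendar years when the as-of date is 31 December, and generalise when it is
not.

Percentages throughout are rendered with half-up rounding
(`format_percentage()`), the convention of printed clinical tables
(e.g. 380/1310 → 29.01, 135/218 → 61.9).

## The synthetic cohort generator

`simulate_cohort()` emits per-patient event streams over a configurable
calendar span (default 2015-2020):

* **Frailty.** Each patient has a latent severity multiplying all
  utilization hazards, drawn log-normal with unit mean
  ($\mu = -\sigma^2/2$, `severity_sigma`, default 1). Unit mean keeps every
  configured rate a marginal expectation; setting `severity_sigma = 0`
  removes heterogeneity entirely, making event counts exactly Poisson — the
  regime in which the calibration tests compare counts to the closed-form
  Poisson mean.
* **Hospital visits** are daily Bernoulli draws at rate
  `baseline_event_rate`/365 × severity (default 0.3 per patient-year — an
  enriched cohort, deliberately: it keeps a 1000-patient simulation rich in
  event patients so lead-time distributions are estimable; real asthma
  cohorts see roughly 1-2% of patients with a hospital visit per year, and
  the rate is a config field). 70% are ED visits, the rest inpatient; each
  relocates to an external facility with probability
  `external_visit_fraction` (default 0.15).
* **Prodrome.** For each hospital visit on day $T$, the outpatient-visit
  hazard is multiplied by `prodrome_intensity` (default 6) over
  $[T-L, T)$ with `prodrome_lead_days` $L$ (default 60), asthma-specific and
  exacerbation-leaning coding becomes more likely, and the corticosteroid
  hazard switches from `steroid_rate_base` (0.6/yr) to
  `steroid_rate_prodrome` (8/yr). The prodromal window is the plantable
  early-warning signal: it is what a risk scan can legitimately detect ahead
  of the visit. The two steroid rates are explicit rather than derived from
  the intensity multiplier so baseline steroid use and prodromal bursts can
  be controlled independently.
* **Codes.** Visits carry principal diagnoses sampled from a configurable
  asthma code menu plus non-asthma noise codes (hypertension, diabetes,
  well-visit, back pain, reflux), so case-finding is non-trivial; some rows
  get a secondary noise code.
* **Deaths** occur at `death_rate`/yr, uniform over the span, and censor all
  later events.
* **Determinism.** Every patient draws from an RNG stream derived from
  `(seed, patient index)`, so the same seed reproduces the table
  byte-for-byte and growing the cohort leaves existing patients unchanged.
  Demographics (`simulate_demographics()`: age uniform 18-90 at span end,
  sex balanced) come from an offset of the same streams.

**What the generator does *not* emulate:** realistic ICD code frequencies,
comorbidity structure, seasonality, care-seeking behaviour, coding drift,
demographic risk gradients, or any calibration to a real health system.
Passing tests on this cohort demonstrate that the statistical machinery is
correct and that a planted prodromal signal is recovered — they say nothing
about predictive performance on real data.

## The prodrome-lead recovery experiment

The design question: does a longer planted lead $L$ produce earlier
warnings? The package's experiment simulates two cohorts identical except
$L \in \{30, 120\}$ (per-patient RNG streams make the hospital-visit days
themselves identical across arms — a paired design) and compares the median
$k$ under one *fixed* linear utilization scorer with each arm's frozen
top-decile threshold.

A fixed scorer, rather than a per-arm retrained model, is deliberate.
Retraining confounds the comparison: the end-of-year label is easier to
predict when prodromes are long (they then overlap the as-of date), so the
$L=30$ arm gets a flatter score distribution and a lower decile threshold,
which background-utilization noise crosses early in the scan window —
inflating $k$ for reasons unrelated to the planted lead, and in practice
inverting the ordering. With a common scorer the first crossing is driven by
the prodromal utilization burst, and the median $k$ ordering follows the
planted lead robustly across seeds.

## Numerical conventions and degenerate inputs

* Cutoff size $\lfloor fN \rfloor$; ties by ascending patient id; threshold
  = lowest flagged score; `apply_cutoff()` refuses empty score sets.
* The daily scan is clipped to the data span: when $T - 365$ predates the
  span start the scan begins at the span start (synthetic patients may lack
  a full year of history; the scan window is then shorter than 365 days).
* Scan granularity is strictly daily — recency features change between
  event dates, so event-date shortcuts would be wrong.
* Empty histories score as the zero-count/sentinel feature vector;
  `predict_at()` is constant over dates for such patients.
* `summarize_leadtimes()` reports SD 0 for a single patient; it refuses
  empty inputs, as does training on single-class labels.
* Dates are ISO-8601 calendar dates end to end; "year" means calendar year.
  The events CSV reader validates each date strictly (rejecting, e.g.,
  month 13) and reports the offending line.

## Problem sizes used by the test-suite experiments

Unit and property tests run on cohorts of 12-600 patients; the shared
fitted pipeline uses 300 patients; the brute-force lead-time oracle is
checked on every event patient of a 600-patient cohort (>100 timelines);
the recovery experiment uses 1000 patients per arm; the bundled acceptance
script runs the full pipeline at 2000 patients. These sizes were chosen so
each check's sampling error is small relative to the effect it verifies
while the whole suite stays fast enough to run routinely.

## Known limitations

* The feature panel is a structural stand-in; no claim is made that it
  approximates any deployed model's feature set.
* The exacerbation code set is a documented guess (configurable).
* Only the *initial* warning is analysed; re-warning dynamics after the
  first hospital visit are out of scope.
* The frozen-threshold convention during the scan is an interpretation (see
  above); a daily-recomputed cutoff would need future data and is not
  offered.
* The generator's independence assumptions (Bernoulli days, one prodrome
  mechanism) make it unsuitable for studying, e.g., calibration drift or
  seasonal confounding.
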