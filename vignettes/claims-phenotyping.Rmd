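---
title: "Phenotyping treated type 2 diabetes from pharmacy claims"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phenotyping treated type 2 diabetes from pharmacy claims}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diabrx)
```

## The problem

Many national health-insurance databases record every reimbursed drug
delivery — patient, date, ATC code — but no diagnosis. For a chronic,
drug-treated disease such as diabetes, treatment itself is then the only
observable phenotype. `diabrx` implements a rule-based case definition on
ATC A10 (hypoglycemic agent) deliveries, separates type 2 from type 1
diabetes without any clinical data, brackets the validity of that
separation without a gold standard, and turns the resulting case set into
annual prevalence, trend and projection figures.

The approach assumes (a) near-universal insurance coverage, so the covered
population is a valid denominator; (b) that pharmacy reimbursement is
recorded essentially without error or missingness; and (c) that treated
diabetes is what matters — undiagnosed patients and those managed by
lifestyle advice alone are invisible to claims and outside the estimand.

## Detection: four delivery-count criteria in two phases

A single A10 delivery is weak evidence: prescription and dispensing errors
occur, and a definition of "3+ deliveries in a year" used by
cross-sectional drug-claim studies would, applied year by year to a
longitudinal window, drop patients with irregular refill behaviour. The
case definition therefore accepts a patient when at least one of four
criteria on yearly delivery counts holds (a *delivery* being a distinct
patient–date pair among A10-prefixed claims, so several claim lines from
one pharmacy visit count once; see `count_deliveries()`):

1. ≥3 deliveries/year in ≥2 years;
2. ≥3 deliveries in one year **and** ≥2/year in ≥2 *other* years;
3. ≥2 deliveries/year in ≥3 years — patients who are often abroad fill
   part of their prescriptions outside the system;
4. ≥3 deliveries in the year of death X, in X−1, or in either of the last
   two window years — decedents and incident cases of the final years
   cannot accumulate two treated years (right truncation).

Years need not be consecutive (treatment gaps are common, and nothing in
the rules requires contiguity); `evaluate_criteria()` offers a
consecutivity-free reading only. Two readings of criterion 2 are possible
because its wording does not say whether the 3-delivery year may also count
as one of the 2-delivery years; the default is the non-overlapping reading
(under which criterion 2 implies criterion 3, and which keeps criterion 2
from collapsing onto criterion 1 cases), with `overlap_criterion2 = TRUE`
as the alternative. Criterion 4's calendar years are generalized to the
last two years of the detection window so the algorithm is portable across
windows.

Detection runs in two phases (`detection_window()`): first over the
reporting window (2000–2006 by default), then, for patients not selected
there — typically dead early in the window — over the full
treatment-history window (1995–2006), re-applying all four criteria.
Patients selected in phase 2 are flagged. For reporting the criterion mix,
each case is attributed a *primary* criterion: the lowest-numbered of 1–3
that matched, and 4 only when nothing else did, reflecting its role as a
truncation rescue (`primary_criterion()`).

## Type separation and the switch-age threshold

Oral hypoglycemic agents (ATC A10B) are not used to treat type 1 diabetes,
so every detected case with an A10B delivery is classified type 2
(step 2). The remaining cases received only insulin (A10A). Among them,
elderly patients starting insulin late are far more likely to be
late-stage type 2 than adult-onset type 1; the age threshold separating
the two is estimated from the data rather than fixed, which makes the
algorithm transferable across countries with different prescribing
practice:

* the *switch cohort* consists of OHA-exposed cases whose treatment ends
  in an insulin-only segment — at least one A10A delivery strictly after
  their last A10B year and no A10B thereafter within the horizon
  (`estimate_switch_threshold()`). Patients alternating OHA and insulin
  never qualify. This persistence definition is a deliberate choice: the
  switch must look permanent within the observed horizon, since a single
  interleaved insulin claim says nothing about a regime change;
* each switcher's age in their first insulin-only year is
  `switch_year - birth_year` (claims data carry no birth dates, only birth
  years, so ages are integer and accurate to ±1 year);
* the threshold is the *floor* of the cohort's mean age (66 when the mean
  is 66.3), matching how such thresholds are quoted and used; a
  nearest-integer option exists.

Step 3 then admits insulin-only cases strictly *older than* the threshold
in the year of their first insulin delivery (`classify_type2()`, with an
inclusive variant). Everyone else is type 1. The known cost of this rule
is that genuinely type-1 patients older than the threshold at first
insulin are misclassified; in the reference population this is bounded by
the size of step 3 itself (260 of 21,068), and prevention practices in
that age class are similar for both types, limiting the impact.

## Validity bounds without a gold standard

No clinical adjudication of the case set exists, but the classifier's
validity can still be bracketed. Let `POPtot` be all detected
treated-diabetes cases, `Pos` those classified type 2, `Neg = POPtot −
Pos`, and let the true type-2 proportion `T2P` lie in a configured range
(0.928–0.967 for the reference inputs; its derivation from per-age-class
composition is not reproducible from published information, so the range
is treated as configuration — `t2p_range_from_classes()` implements the
pooling arithmetic for users who have per-class bounds). With
`D2 = T2P·POPtot` true type-2 and `D1 = POPtot − D2` true type-1 patients:

* `FN ≥ max(0, D2 − Pos)` and
  `FN ≤ min(Neg, D2, fn_cap, min(D1, fp_cap) + D2 − Pos)`,
* `TP = D2 − FN`, `FP = Pos − TP`, `TN = Neg − FN`.

The default caps encode the extreme assignments at the range limits —
`fp_cap = Pos − T2Pmin·POPtot` type-1 patients could at most be hiding
among the positives, `fn_cap = T2Pmax·POPtot − Pos` type-2 patients among
the negatives. The last term of the FN upper bound propagates the FP cap
through the margin `FP = Pos − D2 + FN`; without it the forced extreme
rows (FN = 0 at `T2Pmin`, FP = 0 at `T2Pmax`) would not emerge. On
populations small enough to enumerate, these intervals coincide exactly
with the min/max over all label assignments consistent with the margins
and caps — the test suite checks this against brute-force enumeration.

`D2` is generally non-integer and is used exactly in every ratio; counts
are rounded only for display. Metrics are reported in percent at one
decimal, rounded half-up (`round_half_up()`), the convention of published
validity tables. `metric_intervals()` evaluates a T2P grid and reports the
grid-wide lower bounds — the "always higher than" floors. On the reference
totals (22,178 / 21,068 / 1,110) these floors are SE 98.2%, PPV 97.7%,
NPV 65.9%; our exact arithmetic puts the SPE floor at 63.4% at the 94%
grid row, one display unit below the published 63.5%, consistent with
rounding of unpublished intermediate values. Interior-row TP lower bounds
published for such tables follow a finer per-age-class computation whose
inputs are not printed; the package intentionally does not force agreement
with them.

`discharge_crosscheck()` supports the complementary negative check:
rejected patients should rarely carry a hospital-discharge diabetes code
(ICD-10 roots E10–E14).

## Prevalence, standardization, trends, projection

A classified case is prevalent from the year of their first A10 delivery
(searched over the full horizon, so pre-window history counts) until death
or the end of the reporting period, death year inclusive — the detection
rules themselves treat the death year as a treated year (`case_years()`).
Prevalence is reported only within the reporting period, where case
ascertainment is complete. Annual prevalence divides prevalent cases by
the covered population on 31 December (`annual_prevalence()`);
`stratified_prevalence()` stratifies by sex and ten-year age class
(`0-9` … `90-100`; published age curves use an unstated scheme, so the
breaks are configurable), and `age_standardize()` computes direct
age-standardized rates from any reference weight table, e.g. EU15-style
weights.

Trend summaries: `mean_annual_increase()` is the arithmetic mean of
year-over-year relative changes (a geometric option exists);
`linear_trend_r2()` is the R² of the OLS rate-on-year fit, the check that
a linear-trend projection is sensible. Projection uses Brown's double
exponential smoothing (`fit_des()`): one smoothing constant, two coupled
exponential averages giving a local level and trend, forecasts linear in
the horizon. Brown's one-parameter form is used rather than Holt's
two-parameter variant — with seven annual observations a second parameter
is not identifiable in any meaningful sense. Both smoothed statistics are
initialized at the first observation; alpha is chosen on a grid
(0.05–0.95, step 0.05) by in-sample one-step-ahead RMSE. The reported RMSE
includes the initialization transient, so even an exactly linear series
has non-zero RMSE, while its forecasts continue the line to numerical
precision once the transient has decayed.

Binomial confidence intervals for prevalence are deliberately not
attached: the method behind published intervals for such rates is
typically unstated, and at these population sizes they are narrower than
the systematic uncertainties.

## The synthetic-data generator

`simulate_population()` generates ground-truth-labelled populations so
every stage is testable without real data. It emulates the *structure*
that the algorithm exploits, not pharmacological reality:

* **Type-2 patients** (default 3.5% of the population, matching a
  treated-prevalence level of a Western European adult population in the
  2000s) start oral agents at onset ages ~N(62, 12) truncated to 30–95, in
  an onset year drawn over 1995–2005 with extra mass at the horizon start
  (standing in for cases already prevalent when observation begins).
  Adherent patients (90%) receive `max(3, Poisson(5))` deliveries per full
  treated year; non-adherent ones 0–2. The onset year is partial (1–3
  deliveries).
* **Switchers** (25% of type-2) move to insulin-only treatment at ages
  ~N(66.3, 4), after ≥2 years of oral treatment; they are adherent by
  construction (insulin initiation implies close follow-up). The fraction
  and spread are chosen so a 5,000-person run yields a switch cohort of
  roughly 40–50: the reference population's 229 switchers arose from
  ~21,000 patients, and transplanting that 1.1% fraction to a simulation
  three orders of magnitude smaller would leave the threshold estimator
  with 2–3 observations. At cohort size ~45 and sd 4, the floored mean age
  lands in {65, 66, 67} with high probability, which is what the recovery
  tests assert.
* **Type-1 patients** (0.2%) receive only insulin from young onset ages
  ~N(18, 8) truncated to 1–40, about 6 deliveries/year when adherent. They
  are simulated as incident within the horizon; long-prevalent elderly
  type-1 patients (the group the age rule is known to misclassify) are not
  generated, so simulation PPV slightly flatters the rule — a documented
  optimism, not an accident.
* **Noise users** (2%; 8% in the `high_noise` preset) get 1–2 deliveries
  in a single year — the prescription-error pattern that motivates the
  3-deliveries rule — and must be rejected by all criteria.
* **Travellers** (5% of type-2) get exactly 2 deliveries every treated
  year and are detectable only through criterion 3.
* **Deaths** follow an annual hazard `min(0.4, 2·10⁻⁵·e^(0.1·age))`, a
  Gompertz-like curve giving ~1.5% at 66 and ~6% at 80; claims are
  truncated at the death date.
* **Delivery dates** within a year are evenly anchored with bounded
  jitter, mimicking refills: distinct dates, roughly a month or more
  apart at realistic yearly counts.

All randomness flows from one seed; identical configurations give
byte-identical output. What the generator does *not* emulate: dosage and
DDD structure, co-medication, mixed OHA+insulin maintenance regimes,
coverage churn, migration, or seasonal refill patterns. Passing recovery
tests therefore demonstrate that the algorithm's logic is implemented
correctly and behaves as designed on populations with the assumed
structure — not that its published validity generalizes to any real
population.

Problem sizes used in the test suite: the recovery checks run the
5,000-person `luxembourg_like` preset once; criteria logic is verified
exhaustively over all 4-year count vectors with entries 0–4 and all
death-year placements (3,750 instances); interval arithmetic over 250
random populations of size ≤ 30 by full enumeration. These sizes give
exhaustive or high-confidence coverage of the discrete logic while keeping
a full suite run around a quarter of a minute.

## Numerical choices and degenerate inputs

* Percent displays: half-up rounding at 1 decimal (validity metrics) and
  2 decimals (prevalence); all internal arithmetic is exact.
* `evaluate_criteria()` rejects negative counts; an empty count vector is
  a valid no-claims patient, not an error.
* An empty claims table gives an empty delivery matrix; detection of an
  empty matrix gives an empty case set.
* A case with no A10 claim in the horizon is a hard error in
  `split_by_oha()` (it contradicts how the case was detected), as is an
  insulin-only case with no insulin claim, or a death predating the first
  delivery.
* With no qualifying switcher the threshold falls back to a configured
  default (66) with a message; switchers lacking a birth year are dropped
  from the estimate with a logged count, as are insulin-only cases lacking
  one from step 3 and persons lacking one from age-stratified prevalence.
* `confusion_bounds()` errors when no assignment is consistent with the
  caps (possible with user-supplied caps), and when `t2p` is outside the
  configured range.
* Ties in the alpha grid resolve to the smallest RMSE-minimizing alpha
  (`which.min`).

## Limitations

* Treated prevalence only: undiagnosed and lifestyle-managed diabetes is
  invisible, and drugs bought abroad are missed (criterion 3 mitigates
  but cannot eliminate this).
* The type rule misclassifies type-1 patients older than the threshold at
  first insulin; the error is bounded by the size of step 3.
* The T2P range driving the validity bounds is configuration, not
  estimation; the bounds are only as good as that range.
* Gestational and secondary diabetes are not modelled or separated.
* A10 exposure is read as diabetes treatment; off-label use (e.g. of
  metformin) would inflate the case set.
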