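---
title: "Methods: corticosteroid exposure, withdrawal, and risk in ITP claims"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: corticosteroid exposure, withdrawal, and risk in ITP claims}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of its models and the design
choices behind them. It states no empirical result that the test-suite does
not itself compute.

## The problem

Corticosteroids (CS) are first-line therapy for adult primary immune
thrombocytopenia (ITP), but prolonged or high cumulative exposure carries
well-known harms (infection, diabetes, osteoporosis, peptic ulcer, cataract,
glaucoma, thromboembolism, and more). Administrative claims data can show how
CS are actually prescribed — initial dose, taper, time to withdrawal, switch
to second-line agents such as the thrombopoietin-receptor agonists
eltrombopag (EPAG) and romiplostim (ROMI), or rituximab (RTX) — and, via a
nested case–control design, how adverse-outcome risk relates to CS exposure.
This package implements that analysis chain for claims-shaped tables
(patients, diagnoses, prescriptions, procedures) plus a ground-truth
synthetic generator, since the motivating data source is proprietary.

## Cohort construction

A patient enters the cohort at the first non-suspected ITP diagnosis code.
Inclusion requires age ≥ 20 at entry, enrollment covering a look-back of 6
*calendar months* (entry month minus 6 through the day before entry — months,
not 183 days, because enrollment is month-granular), no CS prescription in
the look-back (new-user design), and no configured exclusion code. Criteria
are applied in a fixed order and each exclusion is tallied once, so the
output mirrors a selection flowchart and every input patient appears exactly
once in cohort ∪ tally. Baseline comorbidity flags are any non-suspected
matching code in the look-back; inpatient status is the flag on the
entry-date diagnosis.

The *assessment period* for exposure runs from entry to the last day of the
last month carrying an ITP code; months carrying a pregnancy-with-ITP code
are removed from all person-time (duration, dose grids, cumulative dose).
The nested case–control at-risk clock instead runs to the end of observation,
following the design's own definition of its assessment window.

## Episodes, doses, withdrawal

**End-date convention.** A prescription supplies days
`date … date + days_supplied − 1`; its exclusive end is
`date + days_supplied`. Two same-class prescriptions merge into one episode
when `next_date − running_end_exclusive ≤ gap_days(class)`; for injectable
classes (ROMI weekly, RTX course-based) the interval between consecutive
prescription *dates* is used. Gap defaults (oral 30 d; EPAG 30; ROMI 28;
RTX 90) are package defaults standing in for unpublished supplementary
values and are fully configurable. Doses of concurrent same-class
prescriptions add, matching the claims practice of splitting a dose across
products.

**PSL equivalence.** CS doses are expressed in prednisolone-equivalent
mg/day using the standard glucocorticoid table (PSL 5 ≡ mPSL 4 ≡
dexamethasone/betamethasone 0.75 ≡ hydrocortisone 20); the factors live in
the configuration because the study's own table is unpublished.

**Pulse and high-dose dexamethasone.** Methylprednisolone 500–1000 mg/day by
injection covering a run of exactly 3 consecutive days, and dexamethasone
20–40 mg/day covering exactly 4 consecutive days, are flagged and carry zero
dose in all dose quantities — but the days still count as CS exposure for
duration, episodes, withdrawal and patterns, because the exclusion in the
source design is scoped to dose assessment only.

**Weekly dose grid.** The grid weeks are the initial prescription, every 2
weeks to Week 20, then 24, 28, 52, 104, 156. The Week-w value is the mean
PSL-equivalent dose over the 7 days *starting* at day `7w` after initiation
(the dose prevailing once w weeks have elapsed); the window convention is not
published, and this choice is the one consistent with the hand-computable
taper example in the test-suite (halving every 2 weeks from 30 mg/day gives
7.5 mg/day at Week 4). The denominator at Week w is patients whose
assessment period covers day `7w`; dose 0 is reported as "no CS
prescription". A patient whose entire window falls in a pregnancy-excluded
month has no defined value that week, which is the one (documented) way the
denominator sequence can fail to be monotone.

**Withdrawal.** CS is withdrawn when ≥ 60 CS-free days follow a
prescription-run end (running maximum of exclusive ends), or when ≥ 60
CS-free days separate the last run end from the assessment end. The event
time is run end minus first CS date; follow-up is capped at 183 days
(6 months) and at the assessment end. Era strata (2015–2019, 2020–2021) are
assigned by the calendar year of CS initiation; starts outside those years
are excluded from the comparison.

## Kaplan–Meier and log-rank

`km_fit()` is a from-scratch product-limit estimator with Greenwood
variance; pointwise CIs use the log(−log) transform (plain Greenwood
optional). The median is the smallest t with S(t) ≤ 0.5; its CI endpoints
are the smallest times at which the upper/lower confidence curves reach 0.5.
Where a curve sits *exactly* at 0.5 this "smallest time" convention differs
from implementations that average across the plateau; the test-suite
compares against `survival::survfit` away from that degenerate case and
against a hand oracle everywhere. Because the source design reports both an
events-only median with IQR and a censored-style median with 95% CI, the
era analysis computes **both** and labels them distinctly: the event-only
summary conditions on withdrawal having occurred; the KM median does not.

## Nested case–control analysis

For each outcome, patients with any of the outcome's exclusion codes in the
look-back are removed from that outcome's at-risk population (prevalent
disease washout); the event time is the first qualifying diagnosis strictly
after entry. Controls are drawn by risk-set (incidence-density) sampling:
at each case's event time t (days since entry — "time-point matching" is
interpreted as matching on the at-risk clock), eligible controls are
patients observed through t and outcome-free through t; future cases are
eligible and may serve repeatedly; up to 5 controls are sampled without
replacement per case with a seeded RNG (cases with no eligible control are
dropped). Sampling is reproducible and independent of input row order — the
input is forced and sorted deterministically before the RNG is seeded.

Exposure is coded from each member's own entry up to the day *before* the
index day: presence (any CS), duration category (<15, 15–<60, ≥60 days) and
cumulative PSL-equivalent dose category (<500, 500–<1500, ≥1500 mg), with
"Untreated" as the reference. A member whose only exposure is flagged
pulse/high-dose days has zero quantified dose but is treated (lowest
non-zero dose bin) rather than "Untreated".

**Estimator.** Although the source design says only "logistic regression",
its published univariate odds ratios exceed the pooled 2×2 cross-products
(infection 2.97 vs ≈ 2.95, diabetes 9.83 vs ≈ 8.31), implying the matched
structure entered the model; the package therefore fits *set-stratified
conditional* logistic regression as the principal estimator, by
Newton–Raphson on the conditional (per-set softmax) likelihood, with Wald
CIs and p-values. Sets whose members are identical on all covariates carry
no information and are dropped; complete separation and non-convergence are
reported as diagnostics, not numbers. The pooled crude OR with Woolf CI is
available as a companion diagnostic. The multivariate model adds gender,
age at entry (continuous — unstated upstream), malignancy, pulmonary
disease and liver disease. No multiple-testing adjustment is applied,
matching the per-outcome reporting of the source design. Outcomes with
fewer than 10 cases are skipped with a logged reason (operationalising the
"only a few instances" exclusion of steroid-induced psychosis).

## The synthetic generator and what a green test establishes

`simulate_claims()` emulates the *structure* the analysis assumes:
month-granular enrollment spans from April 2014 to August 2022, elderly
right-skewed ages (age at entry ≈ median 78, IQR ~68–84, drawn as
`age_max − Gamma(3, 8.7)` truncated to [20, 101] — the exact shape is a free
choice), ~51% female, ~85% ITP-coded, half of eligible ITP patients treated,
75% starting on CS. CS courses are weekly prednisolone scripts at an initial
dose drawn from the observed initial-dose mix (mode 30 mg/day), tapered by a
step schedule (default: halving every 2 weeks), with course length
log-normal (sdlog 1.2) around era-dependent medians of 35 days (starts
before 2020) and 28 days (2020 on); ~3% receive a pulse at the start, ~30%
are re-administered CS later, and EPAG add-on probability rises with
calendar year. Adverse outcomes follow a *discrete-time daily logistic
hazard*: on each at-risk day the event odds are multiplied by the configured
true odds ratio while the patient is CS-exposed ("ever before today" by
default, "currently covered" as an option). This makes the
incidence-density-sampled conditional-logistic OR a known estimand, so the
entire pipeline — generator → cohort → exposure → sampling → regression —
is testable for parameter recovery, which is the package's core validation.

What the generator does **not** emulate: realistic Japanese coding practice,
insurer churn or record duplication, seasonality, confounding by indication
(comorbidities are independent of treatment by default, so adjusted and
unadjusted estimates coincide in truth), dose–response in the outcome model
(the default effect is a single exposure multiplier — duration/cumulative-
dose codings are exercised mechanically, not calibrated), or platelet
counts. A green recovery test therefore establishes internal statistical
correctness of the pipeline under its stated model, not clinical validity
on real claims.

## Numerical and degenerate-input choices

* Bin edges are closed on the left (a duration of exactly 60 days falls in
  "≥60–<90"; a cumulative dose of exactly 500 mg in "≥500–<1500").
* Newton iterations stop on gradient max-norm < 1e-10 or likelihood change
  < 1e-10, error after 25 iterations reporting the gradient norm; |β| > 15
  on any coordinate is reported as complete separation naming the covariate.
* Empty survival input is an error; all-censored input reports the median as
  not reached (NA). A group with zero events still yields a defined log-rank
  statistic; identical groups give χ² = 0, p = 1.
* An era stratum with no CS initiators is omitted with a warning.
* Unknown drug names/classes map to `OTHER_IS` with a warning; invariant
  violations (negative dose, `days_supplied` < 1, unparseable dates) are
  errors naming the rows — never silent drops.

## Known limitations

* Supplementary code lists, gap periods and outcome definitions of the
  motivating study are unpublished; the shipped defaults are documented
  placeholders and all of them are configuration, not code.
* Treatment-line and switch-pattern algorithms upstream are unpublished;
  the line rule (14-day combination window, new line on a class outside the
  current regimen) and the active-set sweep are this package's own
  auditable constructions, with window 0 reproducing strict simultaneity.
* Withdrawal person-time ignores pregnancy-excluded months (they affect
  dose and duration only); the effect is a ≤ 1-month shift for a rare
  configuration.
* `cs_daily_series()` is restricted to the assessment period while the
  case–control at-risk clock runs to observation end; CS prescribed after
  the last ITP-coded month (rare in the generator, possible in real data)
  would not contribute to coded exposure.
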