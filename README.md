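# itpclaims

Pharmacoepidemiological analysis of corticosteroid (CS) use in adult primary
immune thrombocytopenia (ITP) from administrative-claims-shaped tables.

ITP is an autoimmune platelet disorder whose first-line therapy is
corticosteroids; guidelines recommend tapering prednisolone (PSL) within
weeks, yet real-world claims data show a substantial fraction of patients on
long-term CS, with attendant risks of infection, diabetes, osteoporosis and
other adverse outcomes. This package provides the full analysis toolchain a
claims study of this question needs, for epidemiologists and biostatisticians
working with patient / diagnosis / prescription / procedure tables:

* **New-user cohort construction** — first non-suspected ITP diagnosis as the
  entry date, a 6-calendar-month look-back requiring enrollment and no CS
  (steroid washout), age ≥ 20, configurable exclusion code lists, and a
  flowchart-style exclusion tally.
* **Prescription episode construction** — consecutive dispensations of one
  drug class are merged into a continuous episode when the gap from the
  running supply end (`date + days_supplied`) to the next prescription date
  is ≤ the class gap period (date-to-date intervals for injectables).
* **CS dose quantification** — native doses converted to PSL equivalents
  (PSL 5 mg ≡ methylprednisolone 4 mg ≡ dexamethasone 0.75 mg ≡
  hydrocortisone 20 mg); methylprednisolone pulse (0.5–1 g/day × 3 days,
  injection) and high-dose dexamethasone (20–40 mg/day × 4 days) excluded
  from dose assessment; duration bins, a weekly dose grid (initial, every 2
  weeks to Week 20, then 24, 28, 52, 104, 156), and cumulative dose.
* **Time to CS withdrawal** — withdrawal when ≥ 60 CS-free days follow a
  supply end, Kaplan–Meier product-limit estimation (Greenwood variance,
  log–log median CI) within a 6-month cap, log-rank comparison across the
  2015–2019 vs 2020–2021 calendar eras.
* **Treatment patterns** — yearly modality counts, an active-set sweep over
  episode boundaries producing switch/add-on state sequences (with Sankey
  JSON export), and treatment-line derivation with a combination window.
* **Nested case–control risk assessment** — per-outcome look-back washout,
  risk-set (incidence-density) sampling with up to 5 controls per case
  matched on time since entry, exposure coded as presence / duration
  (`<15`, `15–<60`, `≥60` days) / cumulative dose (`<500`, `500–<1500`,
  `≥1500` mg) before the index day, and matched-set **conditional logistic
  regression** fitted by Newton–Raphson on the set-stratified likelihood
  `L(β) = ∏ₛ exp(x_case'β) / Σ_{j∈s} exp(x_j'β)`,
  with Wald CIs, optionally adjusted for gender, age, malignancy, pulmonary
  and liver disease.
* **Synthetic claims generator** — a ground-truth simulator (elderly
  age mix, era-dependent treatment uptake, tapered weekly CS scripts,
  re-administration, switching) whose adverse outcomes follow a
  discrete-time daily logistic hazard with a known odds multiplier while
  CS-exposed, so the whole pipeline's estimand is checkable.

## Worked example

```r
library(itpclaims)
cfg <- itp_config()
sim <- simulate_claims(sim_params(n_patients = 2000L), seed = 42)

sel <- select_cohort(sim$claims, cfg)
sel$exclusions
#>                      criterion n_excluded n_remaining
#> 1:                all_patients          0        2000
#> 2:            no_itp_diagnosis        368        1632
#> 3:           age_below_minimum          0        1632
#> 4:      insufficient_look_back        105        1527
#> 5:             cs_in_look_back         73        1454
#> 6: exclusion_code_in_look_back          0        1454
#> 7:                    selected          0        1454
```

1,454 of 2,000 simulated subscribers qualify as adult new-user ITP patients;
the rest never carry a non-suspected ITP code, lack the 6-month look-back, or
are prevalent steroid users. CS exposure and withdrawal:

```r
co  <- sel$cohort
ser <- cs_daily_series(sim$claims, co, cfg)
wd  <- withdrawal_time(sim$claims, co, cfg)
ana <- withdrawal_analysis(wd, cfg)
ana$fits
#> $`2015-2019`
#> <km_fit> n=379 events=320 median=37 (95% CI 33-43)
#> $`2020-2021`
#> <km_fit> n=125 events=101 median=40 (95% CI 32-44)
ana$logrank$p
#> [1] 0.422
```

Each fit is the all-initiator Kaplan–Meier of days from CS start to
withdrawal (≥ 60 CS-free days), capped at 6 months; at this sample size the
two eras are not distinguishable (log-rank p = 0.42). Nested case–control
for one outcome:

```r
asc   <- ascertain_outcome(co, sim$claims$diagnoses, cfg$outcomes$infection, cfg)
sets  <- sample_risk_sets(asc, cfg$matching_ratio, seed = 43)
coded <- code_exposure(sets, ser, co, cfg)
conditional_logistic(coded, "presence", adjusted = TRUE, cfg)
#>    level n_cases n_controls       or ci_lower ci_upper            p
#> 1:   Yes     376        916 3.153974 2.676426 3.716729 8.539145e-43
```

The adjusted odds ratio of 3.15 (95% CI 2.68–3.72) recovers the generator's
built-in infection effect (true OR 3.0): each case is matched to up to five
controls still at risk at the case's time since entry, and CS exposure is
coded from each member's own entry up to the day before the index day.

## Pipeline and CLI

```sh
Rscript inst/exec/itpclaims --stages simulate,cohort,exposure,patterns,km,ncc \
    --out out/ --seed 1 --n-patients 2000
```

writes the claims CSVs, `cohort.csv`, `exclusion_flow.csv`,
`baseline_table.csv`, `episodes.csv`, `duration_table.csv`, `dose_grid.csv`,
`withdrawal.csv`, `km_curves.csv`, `km_summary.json`, `yearly_counts.csv`,
`lines.csv`, `flows.csv`, `sankey.json`, `incidence.csv`,
`results_{presence,duration,cumdose}.csv` and a `manifest.json` of file
digests (identical config + seed ⇒ identical digests).

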