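# synthetic claims generator: determinism, invariants, stated-world shapes

test_that("identical params and seed give byte-identical tables", {
  p <- sim_params(n_patients = 300L)
  a <- simulate_claims(p, seed = 7)
  b <- simulate_claims(p, seed = 7)
  expect_identical(a$claims$prescriptions, b$claims$prescriptions)
  expect_identical(a$claims$diagnoses, b$claims$diagnoses)
  expect_identical(a$truth$outcomes, b$truth$outcomes)
  c_ <- simulate_claims(p, seed = 8)
  expect_false(identical(a$claims$prescriptions, c_$claims$prescriptions))
})

test_that("n_patients = 0 yields empty tables and truth", {
  s <- simulate_claims(sim_params(n_patients = 0L), seed = 1)
  expect_equal(nrow(s$claims$patients), 0L)
  expect_equal(nrow(s$truth$patients), 0L)
})

test_that("emitted prescriptions respect the record invariants", {
  s <- simulate_claims(sim_params(n_patients = 500L), seed = 3)
  rx <- s$claims$prescriptions
  expect_true(all(rx$days_supplied >= 1L))
  expect_true(all(rx$daily_dose_mg >= 0))
  expect_true(all(rx$route %in% c("oral", "injection")))
  expect_true(all(rx$drug_class %in% c("CS", "EPAG", "ROMI", "RTX",
                                       "OTHER_IS")))
  # validate_claims accepts the whole object
  expect_silent(validate_claims(s$claims))
})

test_that("invalid parameters are rejected", {
  expect_error(sim_params(p_treated_given_itp = 1.2), "probabilities")
  expect_error(sim_params(true_or = c(infection = -1)), "true_or")
  expect_error(sim_params(taper_schedule = data.frame(week = c(0, 2),
                                                      frac = c(0.5, 1))),
               "non-increasing")
})

test_that("taper halving every 2 weeks from 30 mg/day gives week-4 mean 7.5", {
  # hand computation: weeks 0-1 at 30, weeks 2-3 at 15, weeks 4-5 at 7.5;
  # week-4 window = days 22-28 after initiation, all at 7.5 mg/day
  p <- sim_params(
    n_patients = 60L, p_itp = 1, p_suspected_only = 0, p_short_lookback = 0,
    p_prevalent_cs = 0, p_treated_given_itp = 1, p_cs_first = 1,
    initial_dose_mg = 30, initial_dose_probs = 1,
    taper_schedule = data.frame(week = c(0, 2, 4, 6),
                                frac = c(1, 0.5, 0.25, 0.125)),
    cs_duration_median_pre2020 = 400, cs_duration_median_2020on = 400,
    cs_duration_sdlog = 1e-9, p_pulse = 0, p_readmin = 0,
    itp_active_meanlog = log(900), itp_active_sdlog = 1e-9,
    p_pregnancy_itp = 0)
  s <- simulate_claims(p, seed = 21)
  cfg <- itp_config()
  co <- select_cohort(s$claims, cfg)$cohort
  ser <- cs_daily_series(s$claims, co, cfg)
  grid <- weekly_dose_grid(s$claims, ser, co, cfg)
  w4 <- grid$per_patient[week == 4L]
  # always-adherent patients with long courses: exactly 7.5 at week 4
  expect_gt(nrow(w4), 0L)
  expect_true(all(abs(w4$dose - 7.5) < 1e-9))
  w0 <- grid$per_patient[week == 0L]
  expect_true(all(abs(w0$dose - 30) < 1e-9))
})

test_that("ground truth is consistent with emitted claims", {
  s <- simulate_claims(sim_params(n_patients = 400L), seed = 13)
  tp <- s$truth$patients
  rx <- s$claims$prescriptions[drug_class == "CS"]
  first_cs <- rx[, .(first = min(date)), by = patient_id]
  m <- merge(tp[cs_user == TRUE], first_cs, by = "patient_id")
  expect_true(all(m$cs_start == m$first))
  # outcome diagnoses appear for ITP patients at the truth dates
  oc <- s$truth$outcomes[patient_id %in% tp[itp == TRUE, patient_id]]
  if (nrow(oc)) {
    dx <- s$claims$diagnoses
    hit <- merge(oc, dx, by.x = c("patient_id", "date"),
                 by.y = c("patient_id", "date"))
    # every truth outcome inside the observation window has a diagnosis row
    inwin <- merge(oc, tp[, .(patient_id, obs_end_day)], by = "patient_id")
    inwin <- inwin[date <= obs_end_day]
    expect_gte(nrow(hit), nrow(inwin))
  }
})
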