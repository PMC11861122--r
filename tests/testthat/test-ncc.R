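# nested case-control: ascertainment, risk-set sampling, exposure coding,
# conditional logistic regression, crude OR

cfg <- itp_config()
fx <- fixture_small()
sel <- select_cohort(fx, cfg)
co <- sel$cohort
ser <- cs_daily_series(fx, co, cfg)

test_that("outcome ascertainment and look-back washout on the fixture", {
  asc <- ascertain_outcome(co, fx$diagnoses, cfg$outcomes$infection, cfg)
  # F19's infection on 2017-09-15, entry 2017-01-10 -> day 248
  expect_equal(asc[asc$patient_id == "F19", event_time], 248)
  expect_equal(sum(!is.na(asc$event_time)), 1L)
  # diabetes code in look-back removes F19 from the diabetes at-risk set
  asc_dm <- ascertain_outcome(co, fx$diagnoses, cfg$outcomes$diabetes, cfg)
  expect_false("F19" %in% asc_dm$patient_id)
  expect_equal(nrow(asc_dm), nrow(co) - 1L)
})

test_that("risk-set sampling invariants hold over random populations", {
  set.seed(5)
  for (rep in 1:20) {
    n <- 60L
    asc <- data.table::data.table(
      patient_id = sprintf("P%03d", 1:n),
      event_time = ifelse(runif(n) < 0.3,
                          sample.int(300L, n, replace = TRUE), NA_real_),
      atrisk_end = sample(100:600, n, replace = TRUE))
    asc[!is.na(event_time) & event_time > atrisk_end, event_time := NA_real_]
    sets <- sample_risk_sets(asc, 5L, seed = rep)
    if (nrow(sets) == 0L) next
    # each sampled control is at risk at the case's event time
    m <- merge(sets[sets$is_case == FALSE], asc, by = "patient_id")
    expect_true(all(m$atrisk_end >= m$event_time.x))
    expect_true(all(is.na(m$event_time.y) | m$event_time.y > m$event_time.x))
    # 1-5 controls, case not among its controls
    per <- sets[, .(nc = sum(!is_case), case_dup = anyDuplicated(patient_id)),
                by = set_id]
    expect_true(all(per$nc >= 1L & per$nc <= 5L))
    expect_true(all(per$case_dup == 0L))
  }
})

test_that("sampling is reproducible and order-independent", {
  set.seed(77)
  n <- 80L
  asc <- data.table::data.table(
    patient_id = sprintf("Q%03d", 1:n),
    event_time = ifelse(runif(n) < 0.4, sample.int(200L, n, replace = TRUE),
                        NA_real_),
    atrisk_end = sample(150:400, n, replace = TRUE))
  asc[!is.na(event_time) & event_time > atrisk_end, event_time := NA_real_]
  a <- sample_risk_sets(asc, 5L, seed = 1)
  b <- sample_risk_sets(asc, 5L, seed = 1)
  expect_identical(a, b)
  c_ <- sample_risk_sets(asc[sample(nrow(asc))], 5L, seed = 1)
  expect_equal(as.data.frame(a), as.data.frame(c_))
  d <- sample_risk_sets(asc, 5L, seed = 2)
  expect_false(identical(a$patient_id, d$patient_id))
  # future cases may serve as controls for earlier cases
  future_cases <- asc[!is.na(event_time), patient_id]
  ctrl_ids <- a[a$is_case == FALSE, patient_id]
  expect_true(length(intersect(future_cases, ctrl_ids)) > 0L)
})

test_that("a case with no eligible control is dropped", {
  asc <- data.table::data.table(
    patient_id = c("A", "B"),
    event_time = c(50, NA_real_),
    atrisk_end = c(100, 30))   # B leaves observation before day 50
  sets <- sample_risk_sets(asc, 5L, seed = 1)
  expect_equal(nrow(sets), 0L)
})

test_that("matching ratio below 1 is a configuration error", {
  asc <- data.table::data.table(patient_id = "A", event_time = 5,
                                atrisk_end = 10)
  expect_error(sample_risk_sets(asc, 0L, seed = 1), "ratio")
})

test_that("exposure coding matches the printed cut points", {
  sets <- data.table::data.table(
    set_id = 1L,
    patient_id = c("F19", "F11", "F01", "F12"),
    is_case = c(TRUE, FALSE, FALSE, FALSE),
    event_time = 14)
  coded <- code_exposure(sets, ser, co, cfg)
  # 30 mg/day x 14 days: duration ">0-<15" (14 d), cumulative 420 ">0-<500"
  f19 <- coded[coded$patient_id == "F19"]
  expect_equal(f19$cs_days, 14L)
  expect_equal(as.character(f19$dur_bin), ">0-<15")
  expect_equal(f19$cum_mg, 420)
  expect_equal(as.character(f19$cum_bin), ">0-<500")
  # untreated control: Untreated under all codings, not exposed
  f11 <- coded[coded$patient_id == "F11"]
  expect_false(f11$exposed)
  expect_equal(as.character(f11$dur_bin), "Untreated")
  expect_equal(as.character(f11$cum_bin), "Untreated")
  # 10 mg/day x 200 days -> duration ">=60", cumulative 2000 ">=1500"
  long_ser <- data.table::data.table(
    patient_id = "F11", date = as.Date("2016-09-01") + 0:199,
    psl_mg = 10, covered = TRUE)
  coded2 <- code_exposure(
    data.table::data.table(set_id = 1L, patient_id = "F11", is_case = TRUE,
                           event_time = 300),
    long_ser, co, cfg)
  expect_equal(as.character(coded2$dur_bin), ">=60")
  expect_equal(coded2$cum_mg, 2000)
  expect_equal(as.character(coded2$cum_bin), ">=1500")
})

test_that("conditional logistic equals McNemar closed form on 1:1 sets", {
  # 12 case-exposed-only sets vs 6 control-exposed-only sets -> OR 2.0
  mk <- function(n_case_exposed, n_control_exposed, offset = 0L) {
    sets <- lapply(seq_len(n_case_exposed + n_control_exposed), function(s) {
      ce <- s <= n_case_exposed
      data.table::data.table(set_id = s + offset,
                             is_case = c(TRUE, FALSE),
                             exposed = c(ce, !ce))
    })
    data.table::rbindlist(sets)
  }
  d <- mk(12L, 6L)
  fit <- clogit_fit(d$is_case, matrix(as.numeric(d$exposed)), d$set_id)
  expect_equal(unname(fit$or), 2, tolerance = 1e-8)
  # concordant sets are uninformative and dropped
  conc <- data.table::data.table(set_id = rep(100:101, each = 2L),
                                 is_case = rep(c(TRUE, FALSE), 2L),
                                 exposed = TRUE)
  d2 <- rbind(d, conc)
  fit2 <- clogit_fit(d2$is_case, matrix(as.numeric(d2$exposed)), d2$set_id)
  expect_equal(unname(fit2$or), 2, tolerance = 1e-8)
  expect_equal(fit2$n_dropped, 2L)
})

test_that("clogit matches survival::clogit with multiple covariates", {
  skip_if_not_installed("survival")
  set.seed(31)
  d <- data.table::rbindlist(lapply(1:150, function(s) {
    m <- sample(2:6, 1L)
    data.table::data.table(set = s, y = c(TRUE, rep(FALSE, m - 1L)),
                           x1 = rbinom(m, 1L, 0.4), x2 = rnorm(m))
  }))
  f1 <- clogit_fit(d$y, as.matrix(d[, c("x1", "x2")]), d$set)
  f2 <- survival::clogit(y ~ x1 + x2 + strata(set), data = d)
  expect_equal(unname(f1$coef), unname(coef(f2)), tolerance = 1e-8)
  expect_equal(unname(f1$se), unname(sqrt(diag(vcov(f2)))), tolerance = 1e-8)
})

test_that("degenerate designs raise diagnostics", {
  # exposure identical within every set -> no information
  d <- data.table::data.table(set_id = rep(1:5, each = 2),
                              is_case = rep(c(TRUE, FALSE), 5),
                              exposed = TRUE)
  expect_error(clogit_fit(d$is_case, matrix(as.numeric(d$exposed)), d$set_id),
               "no informative")
  # complete separation: case always exposed, controls never
  d2 <- data.table::data.table(set_id = rep(1:20, each = 2),
                               is_case = rep(c(TRUE, FALSE), 20),
                               x = rep(c(1, 0), 20))
  expect_error(clogit_fit(d2$is_case, matrix(d2$x, dimnames = list(NULL, "x")),
                          d2$set_id),
               "separation")
})

test_that("crude OR reproduces hand cross-products with Woolf CI", {
  r <- crude_or(10, 10, 10, 10)
  expect_equal(r$or, 1)
  expect_error(crude_or(0, 5, 5, 5), "zero cell")
  rc <- crude_or(0, 5, 5, 5, correct = TRUE)
  expect_gt(rc$or, 0)
  expect_true(rc$ci_lower < rc$or & rc$or < rc$ci_upper)
})

test_that("run_all_outcomes skips outcomes with too few cases", {
  res <- run_all_outcomes(fx, co, ser, cfg, seed = 1)
  # fixture has at most 1 case per outcome < min_cases = 10
  expect_true(all(res$incidence$n_cases <= 1L))
  expect_true("infection" %in% res$skipped$outcome)
  expect_match(res$skipped$reason[1L], "insufficient cases")
  expect_equal(nrow(res$results), 0L)
})
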