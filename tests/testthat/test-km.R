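# Kaplan-Meier, log-rank, and the era withdrawal analysis

test_that("product-limit estimate matches hand computation", {
  kf <- km_fit(c(5, 10, 15), c(TRUE, TRUE, TRUE))
  expect_equal(kf$curve$surv, c(2 / 3, 1 / 3, 0))
  expect_equal(kf$median, 10)
  # one subject, event at 7
  expect_equal(km_fit(7, TRUE)$median, 7)
  # all censored: median not reached
  expect_true(is.na(km_fit(c(5, 10), c(FALSE, FALSE))$median))
  expect_error(km_fit(numeric(0), logical(0)), "empty")
})

test_that("km_fit agrees with survival::survfit on random fixtures", {
  skip_if_not_installed("survival")
  set.seed(11)
  for (rep in 1:20) {
    n <- sample(5:60, 1L)
    t <- round(rexp(n, 0.02)) + 1
    e <- runif(n) < 0.7
    kf <- km_fit(t, e)
    sf <- survival::survfit(survival::Surv(t, e) ~ 1, conf.type = "log-log")
    expect_equal(kf$curve$surv, sf$surv, tolerance = 1e-12)
    expect_equal(kf$curve$n_risk, sf$n.risk)
    ok <- is.finite(sf$lower)
    expect_equal(kf$curve$lower[ok], sf$lower[ok], tolerance = 1e-9)
    expect_equal(kf$curve$upper[ok], sf$upper[ok], tolerance = 1e-9)
    # median conventions differ only when a curve sits exactly at 0.5
    # (survfit averages over the plateau; we take the smallest such time)
    q <- quantile(sf, 0.5)
    if (min(abs(kf$curve$surv - 0.5)) > 1e-9) {
      expect_equal(unname(kf$median), unname(q$quantile))
    }
    if (sum(e) > 3 && all(is.finite(c(q$lower, q$upper))) &&
        min(abs(kf$curve$lower - 0.5), na.rm = TRUE) > 1e-9 &&
        min(abs(kf$curve$upper - 0.5), na.rm = TRUE) > 1e-9) {
      expect_equal(unname(kf$median_ci[["lower"]]), unname(q$lower))
      expect_equal(unname(kf$median_ci[["upper"]]), unname(q$upper))
    }
  }
})

test_that("censoring-free KM median equals the sample median (step rule)", {
  set.seed(4)
  for (rep in 1:10) {
    t <- sample.int(100L, 21L, replace = TRUE)
    kf <- km_fit(t, rep(TRUE, 21L))
    expect_equal(kf$median, median(t))
  }
})

test_that("log-rank matches the independent O-E/V oracle to 1e-8", {
  set.seed(3)
  ta <- round(rexp(10, 0.02)) + 1; ea <- runif(10) < 0.8
  tb <- round(rexp(10, 0.05)) + 1; eb <- runif(10) < 0.8
  lr <- logrank(ta, ea, tb, eb)
  orc <- oracle_logrank(ta, ea, tb, eb)
  expect_equal(lr$chi_square, orc$chi_square, tolerance = 1e-8)
  expect_equal(lr$p, orc$p, tolerance = 1e-8)
  # label swap invariance
  lr2 <- logrank(tb, eb, ta, ea)
  expect_equal(lr$chi_square, lr2$chi_square, tolerance = 1e-12)
  # identical groups: statistic 0, p = 1
  lr3 <- logrank(ta, ea, ta, ea)
  expect_equal(lr3$chi_square, 0)
  expect_equal(lr3$p, 1)
  expect_error(logrank(numeric(0), logical(0), ta, ea), "non-empty")
})

test_that("clearly separated groups give p < 0.001", {
  ta <- 1:50; tb <- 101:150
  lr <- logrank(ta, rep(TRUE, 50), tb, rep(TRUE, 50))
  expect_lt(lr$p, 0.001)
})

test_that("withdrawal analysis reports both medians per era plus log-rank", {
  cfg <- itp_config()
  fx <- fixture_small()
  co <- select_cohort(fx, cfg)$cohort
  wd <- withdrawal_time(fx, co, cfg)
  ana <- withdrawal_analysis(wd, cfg)
  expect_named(ana$fits, c("2015-2019", "2020-2021"))
  # hand-computed event-only summary for 2020-2021: events at 28 and 30
  eo <- ana$event_only[ana$event_only$era == "2020-2021"]
  expect_equal(eo$n_events, 2L)
  expect_equal(eo$median, 29)
  # survival at 1/3 months present and in [0, 1]
  expect_true(all(ana$surv_at$surv_1m >= 0 & ana$surv_at$surv_1m <= 1))
  expect_true(!is.null(ana$logrank))
  # single-era input: one fit, no test
  expect_warning(
    ana1 <- withdrawal_analysis(wd[wd$era == "2015-2019"], cfg),
    "stratum omitted")
  expect_null(ana1$logrank)
  expect_length(ana1$fits, 1L)
})
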