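# CS exposure: PSL conversion, pulse/HDD flags, episode merging, duration,
# dose grid, cumulative dose, withdrawal

cfg <- itp_config()
fx <- fixture_small()
sel <- select_cohort(fx, cfg)
co <- sel$cohort
ser <- cs_daily_series(fx, co, cfg)

test_that("PSL equivalence uses the standard conversion table", {
  expect_equal(to_psl_equivalent("prednisolone", 30, cfg), 30)
  expect_equal(to_psl_equivalent("dexamethasone", 1.5, cfg), 10)
  expect_equal(to_psl_equivalent("methylprednisolone", 8, cfg), 10)
  expect_error(to_psl_equivalent("mysterysone", 5, cfg), "mysterysone")
})

test_that("pulse and high-dose dexamethasone runs are flagged exactly", {
  rx <- function(name, route, dose, days, date = "2020-01-01") {
    data.table::data.table(patient_id = "X", date = as.Date(date),
                           drug_class = "CS", drug_name = name, route = route,
                           daily_dose_mg = dose, days_supplied = days)
  }
  expect_true(flag_pulse_and_hdd(
    rx("methylprednisolone", "injection", 500, 3L), cfg))
  # oral route: not pulse
  expect_false(flag_pulse_and_hdd(
    rx("methylprednisolone", "oral", 500, 3L), cfg))
  # wrong run length
  expect_false(flag_pulse_and_hdd(
    rx("methylprednisolone", "injection", 500, 4L), cfg))
  # dose out of range
  expect_false(flag_pulse_and_hdd(
    rx("methylprednisolone", "injection", 400, 3L), cfg))
  # high-dose dexamethasone 30 mg/day x 4, either route
  expect_true(flag_pulse_and_hdd(rx("dexamethasone", "oral", 30, 4L), cfg))
  expect_true(flag_pulse_and_hdd(rx("dexamethasone", "injection", 40, 4L),
                                 cfg))
  expect_false(flag_pulse_and_hdd(rx("dexamethasone", "oral", 30, 5L), cfg))
  # three consecutive 1-day scripts form one qualifying pulse run
  three <- data.table::rbindlist(lapply(0:2, function(k) {
    rx("methylprednisolone", "injection", 750, 1L,
       date = as.Date("2020-01-01") + k)
  }))
  expect_true(all(flag_pulse_and_hdd(three, cfg)))
})

test_that("episode merging follows the gap rule", {
  mk <- function(dates, days, class = "CS", route = "oral") {
    data.table::data.table(patient_id = "X", date = as.Date(dates),
                           drug_class = class, drug_name = "prednisolone",
                           route = route, daily_dose_mg = 10,
                           days_supplied = as.integer(days))
  }
  # interval 0 <= gap 14: one episode over days 1-60
  cfg14 <- itp_config(gap_days_by_class = c(CS = 14L, EPAG = 30L, ROMI = 28L,
                                            RTX = 90L, OTHER_IS = 30L))
  e1 <- build_episodes(mk(c("2020-01-01", "2020-01-31"), c(30, 30)), cfg14)
  expect_equal(nrow(e1), 1L)
  expect_equal(as.integer(e1$end - e1$start) + 1L, 60L)
  # interval 29 > gap 14: two episodes
  e2 <- build_episodes(mk(c("2020-01-01", "2020-02-29"), c(30, 30)), cfg14)
  expect_equal(nrow(e2), 2L)
  # single prescription: one episode of length days_supplied
  e3 <- build_episodes(mk("2020-01-01", 30), cfg)
  expect_equal(as.integer(e3$end - e3$start) + 1L, 30L)
  # injectable: interval between prescription DATES
  e4 <- build_episodes(mk(c("2020-01-01", "2020-01-29"), c(7, 7),
                          class = "ROMI", route = "injection"), cfg)
  expect_equal(nrow(e4), 1L)  # 28-day date interval == ROMI gap 28
  e5 <- build_episodes(mk(c("2020-01-01", "2020-01-30"), c(7, 7),
                          class = "ROMI", route = "injection"), cfg)
  expect_equal(nrow(e5), 2L)  # 29 > 28
})

test_that("episode coverage equals the brute-force day-coverage oracle", {
  set.seed(42)
  for (rep in 1:150) {
    rx <- random_rx(sample.int(12L, 1L))
    eps <- build_episodes(rx, cfg)
    orc <- oracle_episodes_oral(rx$date, rx$days_supplied,
                                cfg$gap_days_by_class[["CS"]])
    expect_equal(nrow(eps), nrow(orc))
    expect_equal(as.integer(eps$start), as.integer(orc$start))
    expect_equal(as.integer(eps$end), as.integer(orc$end))
  }
  # idempotent and order-insensitive
  rx <- random_rx(8L)
  a <- build_episodes(rx, cfg)
  b <- build_episodes(rx[sample(nrow(rx))], cfg)
  expect_equal(a, b)
})

test_that("duration counts covered days and honours the printed bin edges", {
  dur <- cs_duration(ser, co, cfg)
  get <- function(id, col) dur[dur$patient_id == id][[col]]
  expect_equal(get("F11", "cs_days"), 0L)
  expect_equal(as.character(get("F11", "duration_bin")), "Untreated")
  # F02: 3 pulse days + 28 oral days; pulse days count toward duration
  expect_equal(get("F02", "cs_days"), 31L)
  # F06: 60-day course minus the 31 excluded March days
  expect_equal(get("F06", "cs_days"), 29L)
  # exact edge: 60 days falls in ">=60-<90"
  expect_equal(as.character(get("F01", "duration_bin")), ">=60-<90")
  expect_equal(as.character(bin_value(c(0, 59, 60, 89, 90, 179, 180, 2219),
                                      cfg$duration_bins_days)),
               c("Untreated", ">0-<60", ">=60-<90", ">=60-<90", ">=90-<180",
                 ">=90-<180", ">=180", ">=180"))
})

test_that("pulse days carry zero dose but remain covered", {
  f02 <- ser[ser$patient_id == "F02"]
  expect_equal(f02$psl_mg[f02$date <= as.Date("2017-03-03")], c(0, 0, 0))
  expect_true(all(f02$covered))
  # the oral 40 mg prednisolone days carry 40
  expect_equal(f02$psl_mg[f02$date == as.Date("2017-03-10")], 40)
})

test_that("weekly dose grid: denominators, zero bin, percentage sums", {
  grid <- weekly_dose_grid(fx, ser, co, cfg)
  tab <- grid$table
  # denominator sequence non-increasing across grid weeks; F06 is excluded
  # here because a fully pregnancy-excluded window makes its week value
  # undefined (the documented edge case breaking strict monotonicity)
  co_np <- co[co$patient_id != "F06"]
  grid_np <- weekly_dose_grid(fx, cs_daily_series(fx, co_np, cfg), co_np, cfg)
  den <- unique(grid_np$table[, c("week", "denom")])
  expect_true(all(diff(den$denom[order(den$week)]) <= 0))
  # percentages sum to 100 per week
  sums <- tapply(tab$pct, tab$week, sum)
  expect_true(all(abs(sums - 100) < 0.1))
  # constant 30 mg/day patient sits in ">=20-<40" at initial and week 2
  pp <- grid$per_patient
  f01 <- pp[pp$patient_id == "F01" & pp$week %in% c(0L, 2L)]
  expect_equal(as.character(f01$bin), rep(">=20-<40", 2L))
  # F03 (high-dose dexamethasone only): dose 0 = "no CS prescription" bin
  f03 <- pp[pp$patient_id == "F03" & pp$week == 0L]
  expect_equal(as.character(f03$bin), "0")
})

test_that("cumulative dose arithmetic and bin edges", {
  who <- data.table::data.table(
    patient_id = c("F01", "F11"),
    up_to = as.Date(c("2016-01-28", "2017-01-01")))
  cd <- cumulative_dose(ser, who, cfg)
  expect_equal(cd$cum_mg, c(30 * 14, 0))  # 14 days at 30 mg/day = 420
  expect_equal(as.character(cd$cum_bin), c(">0-<500", "Untreated"))
  expect_equal(as.character(bin_value(c(499.9, 500, 1499, 1500),
                                      cfg$ncc_cumdose_bins_mg)),
               c(">0-<500", ">=500-<1500", ">=500-<1500", ">=1500"))
})

test_that("withdrawal times follow both clauses of the 60-day rule", {
  wd <- withdrawal_time(fx, co, cfg)
  get <- function(id) wd[wd$patient_id == id]
  # first clause: 30-day script, next at day 95 -> gap 65, event at t=30
  expect_equal(get("F05")$time, 30)
  expect_true(get("F05")$event)
  # second clause: last run ends day 105, assessment end far away
  expect_equal(get("F04")$time, 105)
  expect_true(get("F04")$event)
  # F06: gap to assessment end 51 < 60 -> censored at assessment cap
  expect_false(get("F06")$event)
  expect_equal(get("F06")$time,
               as.numeric(as.Date("2016-05-31") - as.Date("2016-02-10")))
  # era assignment by CS start year
  expect_equal(get("F16")$era, "2020-2021")
  expect_equal(get("F01")$era, "2015-2019")
  # continuous coverage beyond the cap -> censored at 183
  long_rx <- data.table::data.table(
    patient_id = "F01", date = as.Date("2016-01-15") + seq(0, 210, 30),
    drug_class = "CS", drug_name = "prednisolone", route = "oral",
    daily_dose_mg = 10, days_supplied = 30L)
  fx2 <- fx
  fx2$prescriptions <- rbind(
    fx$prescriptions[fx$prescriptions$patient_id != "F01"], long_rx)
  co2 <- data.table::copy(co)
  co2[co2$patient_id == "F01", assessment_end := as.Date("2016-12-31")]
  wd2 <- withdrawal_time(fx2, co2, cfg)
  f01 <- wd2[wd2$patient_id == "F01"]
  expect_false(f01$event)
  expect_equal(f01$time, 183)
})

test_that("duration equals nonzero-dose days plus flagged covered days", {
  dur <- cs_duration(ser, co, cfg)
  per <- ser[, .(nz = sum(psl_mg > 0), cov = .N), by = patient_id]
  m <- merge(dur, per, by = "patient_id")
  expect_equal(m$cs_days, m$cov)
  expect_true(all(m$cs_days >= m$nz))
})
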