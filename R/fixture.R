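# Deterministic hand-written 20-patient fixture. Exercises every analysis
# branch: episode merging and gap splits, methylprednisolone pulse and
# high-dose dexamethasone runs, pregnancy-month exclusion, both withdrawal
# clauses, insufficient look-back, prevalent CS use, suspected-only codes,
# under-age exclusion, EPAG add-on/switch, CS re-administration, splenectomy,
# injectable (date-to-date) merging, treatment-line combos, both calendar
# eras, and a nested case-control outcome with a look-back washout hit.

#' Small deterministic claims fixture
#'
#' Twenty hand-written patients (F01-F20) with known cohort/exposure/pattern
#' results, used throughout the test-suite as a manually verifiable oracle.
#' Eligible cohort: F01-F06, F11-F19. Excluded: F07 (insufficient look-back),
#' F08 (prevalent CS user), F09 (suspected-only ITP), F10 (age < 20),
#' F20 (no ITP code).
#' @return a `claims` object.
#' @export
fixture_small <- function() {
  d <- as.Date
  patients <- data.table::data.table(
    patient_id = sprintf("F%02d", 1:20),
    gender = c("female", "male", "female", "male", "male", "female", "male",
               "female", "male", "female", "female", "male", "female", "male",
               "female", "male", "female", "male", "female", "male"),
    birth_year = c(1950L, 1945L, 1952L, 1948L, 1940L, 1980L, 1955L, 1947L,
                   1951L, 2000L, 1943L, 1949L, 1954L, 1946L, 1953L, 1944L,
                   1950L, 1942L, 1941L, 1956L),
    observation_start = c(rep("2015-01", 6L), "2016-01", rep("2015-01", 13L)),
    observation_end = c("2020-12", rep("2022-08", 19L)))

  dx <- function(pid, date, code = "D69.3", suspected = FALSE,
                 inpatient = FALSE) {
    data.table::data.table(patient_id = pid, date = d(date), code = code,
                           suspected = suspected, inpatient = inpatient)
  }
  diagnoses <- data.table::rbindlist(list(
    dx("F01", "2016-01-15", inpatient = TRUE), dx("F01", "2016-06-10"),
    dx("F01", "2015-12-01", code = "I10"),                # look-back comorbidity
    dx("F02", "2017-03-01"), dx("F02", "2017-08-20"),
    dx("F03", "2018-05-10"), dx("F03", "2018-07-05"),
    dx("F04", "2016-06-01"), dx("F04", "2016-12-15"),
    dx("F05", "2017-01-10"), dx("F05", "2017-06-20"),
    dx("F06", "2016-02-10"), dx("F06", "2016-05-15"),
    dx("F06", "2016-03-05", code = "O99.1"),              # pregnancy with ITP
    dx("F07", "2016-03-10"),                              # < 6 months look-back
    dx("F08", "2017-05-01"), dx("F08", "2017-09-01"),
    dx("F09", "2016-04-01", suspected = TRUE),            # suspected only
    dx("F10", "2018-06-01"),                              # age 18 at entry
    dx("F11", "2016-09-01"), dx("F11", "2017-02-10"),
    dx("F12", "2019-02-01"), dx("F12", "2019-07-10"),
    dx("F13", "2018-01-10"), dx("F13", "2018-07-15"),
    dx("F14", "2017-02-01"), dx("F14", "2017-09-10"),
    dx("F15", "2019-03-01"), dx("F15", "2019-06-10"),
    dx("F16", "2020-06-01"), dx("F16", "2020-12-10"),
    dx("F17", "2021-03-01"), dx("F17", "2021-10-05"),
    dx("F18", "2019-08-01"), dx("F18", "2020-01-15"),
    dx("F19", "2017-01-10"), dx("F19", "2017-12-01"),
    dx("F19", "2016-12-01", code = "E11"),                # diabetes washout hit
    dx("F19", "2017-09-15", code = "A49"),                # infection outcome
    dx("F20", "2016-05-01", code = "Z00")))

  rx <- function(pid, date, class = "CS", name = "prednisolone",
                 route = "oral", dose = 30, days = 30L) {
    data.table::data.table(patient_id = pid, date = d(date),
                           drug_class = class, drug_name = name, route = route,
                           daily_dose_mg = dose, days_supplied = days)
  }
  prescriptions <- data.table::rbindlist(list(
    # F01: two abutting 30-day scripts -> one 60-day episode, event at t=60
    rx("F01", "2016-01-15"), rx("F01", "2016-02-14"),
    # F02: mPSL pulse (flagged) then tapered oral PSL
    rx("F02", "2017-03-01", name = "methylprednisolone", route = "injection",
       dose = 500, days = 3L),
    rx("F02", "2017-03-04", dose = 40, days = 14L),
    rx("F02", "2017-03-18", dose = 40, days = 14L),
    # F03: high-dose dexamethasone run (flagged)
    rx("F03", "2018-05-10", name = "dexamethasone", dose = 30, days = 4L),
    # F04: 45-day gap > 30 -> two episodes; second clause withdrawal at t=105
    rx("F04", "2016-06-01", dose = 10), rx("F04", "2016-08-15", dose = 10),
    # F05: 65-day gap -> first-clause withdrawal at t=30
    rx("F05", "2017-01-10"), rx("F05", "2017-04-15"),
    # F06: 60-day course spanning the excluded pregnancy month (March 2016)
    rx("F06", "2016-02-10", dose = 20, days = 60L),
    # F08: prevalent user (CS inside look-back)
    rx("F08", "2017-04-01", dose = 10, days = 14L),
    rx("F08", "2017-05-01", dose = 10, days = 14L),
    # F12: CS then EPAG add-on -> CS, CS|EPAG, EPAG states
    rx("F12", "2019-02-01"), rx("F12", "2019-03-03"),
    rx("F12", "2019-03-15", class = "EPAG", name = "eltrombopag", dose = 25),
    rx("F12", "2019-04-14", class = "EPAG", name = "eltrombopag", dose = 25),
    rx("F12", "2019-05-14", class = "EPAG", name = "eltrombopag", dose = 25),
    # F13: CS -> EPAG -> CS re-administration
    rx("F13", "2018-01-10"),
    rx("F13", "2018-02-20", class = "EPAG", name = "eltrombopag", dose = 25),
    rx("F13", "2018-03-22", class = "EPAG", name = "eltrombopag", dose = 25),
    rx("F13", "2018-06-01", dose = 10),
    # F14: CS then splenectomy (procedure below)
    rx("F14", "2017-02-01"),
    # F15: weekly romiplostim injections, date-to-date merging
    rx("F15", "2019-03-01", class = "ROMI", name = "romiplostim",
       route = "injection", dose = 250, days = 7L),
    rx("F15", "2019-03-08", class = "ROMI", name = "romiplostim",
       route = "injection", dose = 250, days = 7L),
    rx("F15", "2019-03-15", class = "ROMI", name = "romiplostim",
       route = "injection", dose = 250, days = 7L),
    rx("F15", "2019-03-22", class = "ROMI", name = "romiplostim",
       route = "injection", dose = 250, days = 7L),
    # F16: 2020 era, two 14-day scripts -> event at t=28
    rx("F16", "2020-06-01", days = 14L), rx("F16", "2020-06-15", days = 14L),
    # F17: 2021 era, single 30-day script -> event at t=30
    rx("F17", "2021-03-01", dose = 20),
    # F18: CS + EPAG within the 14-day combo window -> line 1 "CS|EPAG"
    rx("F18", "2019-08-01"),
    rx("F18", "2019-08-08", class = "EPAG", name = "eltrombopag", dose = 25),
    # F19: short CS course before the infection outcome
    rx("F19", "2017-01-10")))

  procedures <- data.table::data.table(
    patient_id = "F14", date = d("2017-05-10"), procedure = "splenectomy")

  validate_claims(as_claims(list(
    patients = patients, diagnoses = diagnoses,
    prescriptions = prescriptions, procedures = procedures)))
}
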