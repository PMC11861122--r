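# New-user cohort construction: selection flowchart, entry dates, assessment
# periods (with pregnancy-month exclusion), and baseline covariates.

lookback_start_of <- function(entry, lookback_months) {
  add_months(month_start(entry), -as.integer(lookback_months))
}

#' Apply the patient-selection flow and derive the analysis cohort
#'
#' Inclusion requires at least one non-suspected ITP diagnosis code, age >=
#' `min_age` (default 20) at entry, enrollment covering the full look-back
#' window (entry month minus `lookback_months` calendar months), no CS
#' prescription in the look-back window (new-user / steroid-washout design),
#' and none of the configured cohort exclusion codes in the look-back.
#' Criteria are applied in that order and every excluded patient is tallied
#' under the first criterion that removed them, mirroring a selection
#' flowchart.
#'
#' @param claims a `claims` object from [read_claims()] / [simulate_claims()].
#' @param config an [itp_config()] object.
#' @return list with `cohort` (one row per selected patient: entry date, age,
#'   assessment end, excluded pregnancy months, baseline covariate flags) and
#'   `exclusions` (per-criterion tally; every input patient appears exactly
#'   once in cohort or tally).
#' @export
select_cohort <- function(claims, config = itp_config()) {
  cl <- config$code_lists
  if (length(cl$itp) == 0L) {
    stop("configuration error: empty ITP code list", call. = FALSE)
  }
  p <- data.table::copy(claims$patients)
  dxn <- claims$diagnoses[suspected == FALSE]
  itp_dx <- dxn[code %in% cl$itp]
  entry_dt <- itp_dx[, .(entry_date = min(date),
                         inpatient_entry = any(inpatient[date == min(date)])),
                     by = patient_id]
  p <- entry_dt[p, on = "patient_id"]
  p[, obs_start_day := month_start(observation_start)]
  p[, obs_end_day := month_end(observation_end)]
  p[, age_at_entry := year_of(entry_date) - birth_year]

  n0 <- nrow(p)
  flow <- list()
  drop_step <- function(p, keep, label) {
    flow[[label]] <<- sum(!keep)
    p[keep]
  }
  p <- drop_step(p, !is.na(p$entry_date), "no_itp_diagnosis")
  p <- drop_step(p, p$age_at_entry >= config$min_age, "age_below_minimum")
  p[, lookback_start := lookback_start_of(entry_date, config$lookback_months)]
  p <- drop_step(p, p$lookback_start >= p$obs_start_day &
                   p$entry_date <= p$obs_end_day, "insufficient_look_back")
  cs_rx <- claims$prescriptions[drug_class == "CS",
                                .(patient_id, rx_date = date)]
  prev <- cs_rx[p, on = .(patient_id, rx_date >= lookback_start,
                          rx_date < entry_date),
                .(n_cs = sum(!is.na(x.rx_date))), by = .EACHI]$n_cs
  p <- drop_step(p, prev == 0L, "cs_in_look_back")
  if (length(cl$cohort_exclusions)) {
    ex_dx <- dxn[code %in% cl$cohort_exclusions,
                 .(patient_id, dx_date = date)]
    hits <- ex_dx[p, on = .(patient_id, dx_date >= lookback_start,
                            dx_date < entry_date),
                  .(n_ex = sum(!is.na(x.dx_date))), by = .EACHI]$n_ex
    p <- drop_step(p, hits == 0L, "exclusion_code_in_look_back")
  } else {
    flow[["exclusion_code_in_look_back"]] <- 0L
  }

  # assessment period and pregnancy-month exclusion
  ap <- assessment_periods(p, claims$diagnoses, config)
  p <- ap[p, on = "patient_id"]

  # baseline comorbidity flags: any non-suspected matching code in look-back
  concepts <- setdiff(names(cl), c("itp", "pregnancy_itp", "cohort_exclusions"))
  for (co in concepts) {
    co_dx <- dxn[code %in% cl[[co]], .(patient_id, dx_date = date)]
    hits <- co_dx[p, on = .(patient_id, dx_date >= lookback_start,
                            dx_date < entry_date),
                  .(k = sum(!is.na(x.dx_date))), by = .EACHI]$k
    p[, (paste0("cov_", co)) := hits > 0L]
  }
  p[, inpatient_entry := isTRUE_v(inpatient_entry)]
  cohort <- p[, c("patient_id", "gender", "birth_year", "entry_date",
                  "age_at_entry", "inpatient_entry", "lookback_start",
                  "assessment_end", "obs_end_day", "excluded_months",
                  grep("^cov_", names(p), value = TRUE)), with = FALSE]
  data.table::setorder(cohort, patient_id)
  excl_n <- unlist(flow)
  exclusions <- data.table::data.table(
    criterion = c("all_patients", names(flow), "selected"),
    n_excluded = c(0L, unname(excl_n), 0L),
    n_remaining = c(n0, n0 - cumsum(unname(excl_n)), nrow(cohort)))
  list(cohort = cohort, exclusions = exclusions)
}

isTRUE_v <- function(x) !is.na(x) & x

# vectorized assessment periods for a selected patient table
assessment_periods <- function(p, diagnoses, config) {
  cl <- config$code_lists
  itp_dx <- diagnoses[suspected == FALSE & code %in% cl$itp,
                      .(patient_id, date)]
  last_itp <- itp_dx[p[, .(patient_id, entry_date)], on = "patient_id"
                     ][date >= entry_date,
                       .(assessment_end = month_end(max(date))),
                       by = patient_id]
  preg <- diagnoses[code %in% cl$pregnancy_itp,
                    .(excluded_months = list(sort(unique(ym(date))))),
                    by = patient_id]
  out <- preg[last_itp, on = "patient_id"]
  out[, excluded_months := lapply(excluded_months,
                                  function(m) if (is.null(m)) character(0) else m)]
  out
}

#' Assessment period for a single cohort patient
#'
#' The assessment period runs from the entry date (first non-suspected ITP
#' diagnosis) to the last day of the last month carrying an ITP code; months
#' carrying a pregnancy-with-ITP code are excluded from all person-time.
#'
#' @param patient_id patient identifier.
#' @param diagnoses the diagnoses table.
#' @param config an [itp_config()] object.
#' @return list with `entry_date`, `assessment_end`, `excluded_months`
#'   (character vector of "YYYY-MM").
#' @export
assessment_period <- function(patient_id, diagnoses, config = itp_config()) {
  pid <- patient_id
  cl <- config$code_lists
  itp_dx <- diagnoses[diagnoses$patient_id == pid &
                        diagnoses$suspected == FALSE &
                        diagnoses$code %in% cl$itp, ]
  if (nrow(itp_dx) == 0L) stop("patient has no qualifying ITP diagnosis")
  entry <- min(itp_dx$date)
  preg <- diagnoses[diagnoses$patient_id == pid &
                      diagnoses$code %in% cl$pregnancy_itp, ]
  list(entry_date = entry,
       assessment_end = month_end(max(itp_dx$date)),
       excluded_months = sort(unique(ym(preg$date))))
}

# the set of calendar days of the assessment period, minus excluded months
assessment_days <- function(entry, assessment_end, excluded_months) {
  if (is.na(entry) || assessment_end < entry) return(as.Date(character(0)))
  days <- seq(entry, assessment_end, by = "day")
  if (length(excluded_months)) days <- days[!ym(days) %in% excluded_months]
  days
}

#' Baseline characteristics summary
#'
#' Tabulates the cohort the way a baseline-characteristics table is printed:
#' counts and percentages for gender and inpatient status (percentages sum to
#' 100 within each), age summary statistics (mean, SD, median, IQR, min, max),
#' and per-comorbidity counts with duplicate counting (a patient may appear
#' under several comorbidities).
#'
#' @param cohort the `cohort` table from [select_cohort()].
#' @return a long data.table: `variable`, `level`, `n`, `pct`, `value`.
#' @export
baseline_table <- function(cohort) {
  stopifnot(nrow(cohort) > 0L)
  n <- nrow(cohort)
  pct <- function(k) round(100 * k / n, 2)
  rows <- list(
    data.table::data.table(variable = "all_patients", level = "", n = n,
                           pct = 100, value = NA_real_))
  gn <- table(factor(cohort$gender, levels = c("female", "male")))
  rows$gender <- data.table::data.table(
    variable = "gender", level = names(gn), n = as.integer(gn),
    pct = pct(as.integer(gn)), value = NA_real_)
  age <- cohort$age_at_entry
  stats_ <- c(mean = mean(age), sd = stats::sd(age),
              median = stats::median(age),
              q1 = unname(stats::quantile(age, 0.25, type = 2)),
              q3 = unname(stats::quantile(age, 0.75, type = 2)),
              min = min(age), max = max(age))
  rows$age <- data.table::data.table(
    variable = "age", level = names(stats_), n = NA_integer_,
    pct = NA_real_, value = round(unname(stats_), 2))
  inp <- table(factor(cohort$inpatient_entry, levels = c(TRUE, FALSE)))
  rows$inpatient <- data.table::data.table(
    variable = "inpatient", level = c("inpatient", "outpatient"),
    n = as.integer(inp), pct = pct(as.integer(inp)), value = NA_real_)
  covs <- grep("^cov_", names(cohort), value = TRUE)
  if (length(covs)) {
    k <- vapply(covs, function(v) sum(cohort[[v]]), integer(1))
    rows$comorbidity <- data.table::data.table(
      variable = "comorbidity", level = sub("^cov_", "", covs),
      n = unname(k), pct = pct(unname(k)), value = NA_real_)
  }
  data.table::rbindlist(rows)
}
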