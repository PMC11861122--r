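# CS exposure quantification: prednisolone-equivalent conversion, pulse /
# high-dose-dexamethasone flagging, episode merging with gap periods, daily
# dose series, duration, the weekly dose grid, cumulative dose, withdrawal.
#
# Conventions (all date arithmetic in calendar days):
#   end_exclusive = prescription date + days_supplied
#   covered days  = date ... date + days_supplied - 1
#   merge rule    : next_start - running end_exclusive <= gap  (oral)
#                   next_start - previous start        <= gap  (injectables)
#   withdrawal    : gap >= withdrawal_gap_days (measured from end_exclusive)

# long (patient_id, month) table of pregnancy-excluded months
excluded_month_table <- function(tab) {
  len <- vapply(tab$excluded_months, length, 1L)
  idx <- which(len > 0L)
  if (!length(idx)) {
    return(data.table::data.table(patient_id = character(0),
                                  month = character(0)))
  }
  data.table::data.table(
    patient_id = rep(tab$patient_id[idx], len[idx]),
    month = as.character(unlist(tab$excluded_months[idx])))
}

#' Ordered bin labels for a "zero plus open-ended cuts" binning
#' @param cuts strictly increasing positive cut points.
#' @param zero_label label of the zero bin.
#' @return character vector of length `length(cuts) + 2`.
#' @keywords internal
bin_labels <- function(cuts, zero_label = "Untreated") {
  f <- function(x) vapply(x, format, "", trim = TRUE, scientific = FALSE)
  inner <- if (length(cuts) > 1L) {
    paste0(">=", f(cuts[-length(cuts)]), "-<", f(cuts[-1L]))
  } else character(0)
  c(zero_label, paste0(">0-<", f(cuts[1L])), inner,
    paste0(">=", f(cuts[length(cuts)])))
}

#' Assign values to the bins of [bin_labels()]
#'
#' Zero maps to the zero bin; cut points are closed on the left (a value equal
#' to a cut point falls in the bin it opens).
#' @param x non-negative numeric vector.
#' @param cuts strictly increasing positive cut points.
#' @param zero_label label of the zero bin.
#' @return factor with the full label set as levels.
#' @export
bin_value <- function(x, cuts, zero_label = "Untreated") {
  labs <- bin_labels(cuts, zero_label)
  idx <- findInterval(x, cuts) + 2L
  idx[x == 0] <- 1L
  factor(labs[idx], levels = labs)
}

#' Convert a native corticosteroid dose to prednisolone equivalents
#'
#' Multiplies the native compound mg/day by the configured equivalence factor
#' (mg prednisolone per mg of drug). Prednisolone's factor is exactly 1.
#' @param drug_name character vector of drug names.
#' @param daily_dose_mg native daily dose, mg/day.
#' @param config an [itp_config()] object.
#' @return numeric vector, mg/day prednisolone-equivalent.
#' @export
#' @examples
#' to_psl_equivalent("dexamethasone", 1.5, itp_config())  # 10
to_psl_equivalent <- function(drug_name, daily_dose_mg,
                              config = itp_config()) {
  fac <- config$psl_equivalence[drug_name]
  if (anyNA(fac)) {
    stop("configuration error: no PSL equivalence factor for drug(s): ",
         paste(unique(drug_name[is.na(fac)]), collapse = ", "), call. = FALSE)
  }
  unname(fac) * daily_dose_mg
}

#' Flag methylprednisolone pulse and high-dose dexamethasone prescriptions
#'
#' Pulse therapy: methylprednisolone 500-1000 mg/day, injection route only,
#' covering a run of exactly 3 consecutive days. High-dose dexamethasone:
#' 20-40 mg/day (native mg), oral or injection, a run of exactly 4 consecutive
#' days. A prescription is flagged when all its covered days lie in a
#' qualifying run. Flagged days are excluded from dose quantification but
#' still count as CS exposure for duration, episodes and patterns.
#'
#' @param prescriptions prescriptions table (any classes; only CS rows can be
#'   flagged).
#' @param config an [itp_config()] object.
#' @return logical vector along the rows of `prescriptions`.
#' @export
flag_pulse_and_hdd <- function(prescriptions, config = itp_config()) {
  rx <- data.table::as.data.table(prescriptions)
  flag <- rep(FALSE, nrow(rx))
  mark_runs <- function(cand, run_len) {
    if (!any(cand)) return()
    cd <- data.table::data.table(row = which(cand),
                                 patient_id = rx$patient_id[cand],
                                 date = rx$date[cand],
                                 days_supplied = rx$days_supplied[cand])
    cd <- cd[, .(day = as.integer(date) + seq_len(days_supplied) - 1L),
             by = .(row, patient_id)]
    days <- unique(cd[, .(patient_id, day)])
    data.table::setorder(days, patient_id, day)
    days[, run := cumsum(c(TRUE, diff(day) != 1L)), by = patient_id]
    days[, good := .N == run_len, by = .(patient_id, run)]
    good_days <- days[good == TRUE, .(patient_id, day, good)]
    cd <- good_days[cd, on = .(patient_id, day)]
    # a prescription qualifies if every covered day lies in a qualifying run
    per_row <- cd[, .(all_in = all(!is.na(good))), by = row]
    flag[per_row[all_in == TRUE, row]] <<- TRUE
  }
  pr <- config$pulse_dose_range_mg
  cand_pulse <- rx$drug_class == "CS" & rx$drug_name == config$pulse_drug &
    rx$route == "injection" &
    rx$daily_dose_mg >= pr[1L] & rx$daily_dose_mg <= pr[2L]
  mark_runs(cand_pulse, config$pulse_run_days)
  hr <- config$hdd_dose_range_mg
  cand_hdd <- rx$drug_class == "CS" & rx$drug_name == config$hdd_drug &
    rx$daily_dose_mg >= hr[1L] & rx$daily_dose_mg <= hr[2L]
  mark_runs(cand_hdd, config$hdd_run_days)
  flag
}

#' Merge prescriptions into continuous treatment episodes
#'
#' Within one patient and drug class, consecutive prescriptions are combined
#' into one episode when the interval from the running end date
#' (date + days_supplied, exclusive) of the previous prescriptions to the next
#' prescription date is less than or equal to the class gap period. For
#' injectable classes (`config$injection_classes`) the interval between
#' consecutive prescription dates is used instead.
#'
#' @param prescriptions prescriptions table (one or more patients/classes).
#' @param config an [itp_config()] object.
#' @return data.table: `patient_id`, `drug_class`, `episode`, `start`,
#'   `end` (inclusive last covered day), `end_exclusive`, `n_rx`.
#' @export
build_episodes <- function(prescriptions, config = itp_config()) {
  if (nrow(prescriptions) == 0L) {
    return(data.table::data.table(
      patient_id = character(0), drug_class = character(0),
      episode = integer(0), start = as.Date(character(0)),
      end = as.Date(character(0)), end_exclusive = as.Date(character(0)),
      n_rx = integer(0)))
  }
  rx <- data.table::as.data.table(prescriptions)[
    , .(patient_id, drug_class, date, days_supplied)]
  data.table::setorder(rx, patient_id, drug_class, date, days_supplied)
  rx[, end_excl := as.integer(date) + days_supplied]
  rx[, gap_allowed := config$gap_days_by_class[drug_class]]
  rx[, inj_rule := drug_class %in% config$injection_classes]
  rx[, run_end := cummax(end_excl), by = .(patient_id, drug_class)]
  rx[, prev_ref := data.table::shift(
    ifelse(inj_rule, as.integer(date), run_end)),
    by = .(patient_id, drug_class)]
  rx[, new_ep := is.na(prev_ref) |
       (as.integer(date) - prev_ref) > gap_allowed]
  rx[, episode := cumsum(new_ep), by = .(patient_id, drug_class)]
  eps <- rx[, .(start = min(date),
                end_exclusive = as.Date(max(end_excl), origin = "1970-01-01"),
                n_rx = .N),
            by = .(patient_id, drug_class, episode)]
  eps[, end := end_exclusive - 1L]
  eps[, .(patient_id, drug_class, episode, start, end, end_exclusive, n_rx)]
}

#' Per-day prednisolone-equivalent CS dose series for cohort patients
#'
#' Expands CS prescriptions to covered calendar days within each patient's
#' assessment period (pregnancy-excluded months removed). Doses of concurrent
#' prescriptions add. Days covered only by flagged pulse / high-dose
#' dexamethasone prescriptions carry dose 0 but remain covered.
#'
#' @param claims a `claims` object.
#' @param cohort the cohort table from [select_cohort()].
#' @param config an [itp_config()] object.
#' @return data.table: `patient_id`, `date`, `psl_mg` (dose-assessment value),
#'   `covered` (always TRUE; rows exist only for covered days).
#' @export
cs_daily_series <- function(claims, cohort, config = itp_config()) {
  rx <- claims$prescriptions[drug_class == "CS" &
                               patient_id %in% cohort$patient_id]
  if (nrow(rx) == 0L) {
    return(data.table::data.table(patient_id = character(0),
                                  date = as.Date(character(0)),
                                  psl_mg = numeric(0), covered = logical(0)))
  }
  rx <- data.table::copy(rx)
  rx[, flagged := flag_pulse_and_hdd(rx, config)]
  rx[, psl := to_psl_equivalent(drug_name, daily_dose_mg, config)]
  long <- rx[, .(date = date + seq_len(days_supplied) - 1L,
                 psl = psl, flagged = flagged),
             by = .(patient_id, rxid = seq_len(nrow(rx)))]
  series <- long[, .(psl_mg = sum(psl[!flagged]), covered = TRUE),
                 by = .(patient_id, date)]
  win <- cohort[, .(patient_id, entry_date, assessment_end, excluded_months)]
  series <- series[win, on = "patient_id", nomatch = NULL]
  series <- series[date >= entry_date & date <= assessment_end]
  # drop pregnancy-excluded months
  exl <- excluded_month_table(win)
  if (nrow(exl)) {
    series[, month := ym(date)]
    series <- series[!exl, on = .(patient_id, month)]
    series[, month := NULL]
  }
  series[, c("entry_date", "assessment_end", "excluded_months") := NULL]
  data.table::setorder(series, patient_id, date)
  series[]
}

#' Total CS prescription duration per cohort patient
#'
#' Duration is the number of CS-covered days inside the assessment period
#' (pregnancy months excluded); pulse / high-dose days count. Returns both the
#' day count and the descriptive duration bin.
#'
#' @param series output of [cs_daily_series()].
#' @param cohort the cohort table.
#' @param config an [itp_config()] object.
#' @return data.table: `patient_id`, `cs_days`, `duration_bin` for every
#'   cohort patient (untreated patients have `cs_days = 0`).
#' @export
cs_duration <- function(series, cohort, config = itp_config()) {
  dur <- series[, .(cs_days = .N), by = patient_id]
  out <- dur[cohort[, .(patient_id)], on = "patient_id"]
  out[is.na(cs_days), cs_days := 0L]
  out[, duration_bin := bin_value(cs_days, config$duration_bins_days)]
  data.table::setorder(out, patient_id)
  out[]
}

#' Weekly prescribed-dose grid among CS-treated patients
#'
#' For each grid week the mean prednisolone-equivalent dose over the 7-day
#' window starting on day `7 w` after initiation is binned (so the Week-2
#' value is the dose prevailing once 2 weeks have elapsed); week 0
#' ("initial") is the PSL-equivalent daily dose of the first non-flagged CS
#' prescription. The denominator at week `w` is the number of CS-treated
#' patients whose assessment period covers day `7 w` after initiation; a dose
#' of 0 means "no CS prescription" in that window. Window days falling in
#' pregnancy-excluded months or beyond the assessment end are skipped (the
#' mean is over the remaining window days).
#'
#' @param claims a `claims` object.
#' @param series output of [cs_daily_series()].
#' @param cohort the cohort table.
#' @param config an [itp_config()] object.
#' @return list: `per_patient` (patient x week mean dose, long) and `table`
#'   (week x dose bin, `n` and `pct`).
#' @export
weekly_dose_grid <- function(claims, series, cohort, config = itp_config()) {
  rx <- claims$prescriptions[drug_class == "CS" &
                               patient_id %in% cohort$patient_id]
  if (nrow(rx) == 0L) stop("no CS prescriptions in cohort", call. = FALSE)
  rx <- data.table::copy(rx)
  rx[, flagged := flag_pulse_and_hdd(rx, config)]
  first_rx <- rx[flagged == FALSE][order(patient_id, date),
                                   .SD[1L], by = patient_id]
  init <- rx[order(patient_id, date), .(init_date = date[1L]), by = patient_id]
  first_dose <- first_rx[, .(patient_id,
                             init_dose = to_psl_equivalent(
                               drug_name, daily_dose_mg, config))]
  init <- first_dose[init, on = "patient_id"]
  init[is.na(init_dose), init_dose := 0]
  win <- cohort[, .(patient_id, assessment_end, excluded_months)]
  init <- win[init, on = "patient_id", nomatch = NULL]

  weeks <- setdiff(config$week_grid, 0L)
  exl <- excluded_month_table(init)
  vals <- list()
  vals$initial <- init[, .(patient_id, week = 0L, dose = init_dose)]
  for (w in weeks) {
    elig <- init[assessment_end >= init_date + 7L * w]
    if (nrow(elig) == 0L) next
    wdays <- elig[, .(date = init_date + (7L * w):(7L * w + 6L)),
                  by = .(patient_id, assessment_end, init_date)]
    wdays <- wdays[date <= assessment_end]
    wdays[, month := ym(date)]
    if (nrow(exl)) wdays <- wdays[!exl, on = .(patient_id, month)]
    wdays <- series[, .(patient_id, date, psl_mg)][
      wdays[, .(patient_id, date)], on = .(patient_id, date)]
    wdays[is.na(psl_mg), psl_mg := 0]
    vals[[as.character(w)]] <- wdays[, .(week = w, dose = mean(psl_mg)),
                                     by = patient_id]
  }
  per_patient <- data.table::rbindlist(vals, use.names = TRUE)
  per_patient[, bin := bin_value(dose, config$dose_bins_mg_per_day,
                                 zero_label = "0")]
  tab <- per_patient[, .(n = .N), by = .(week, bin)]
  tab <- tab[data.table::CJ(week = unique(per_patient$week),
                            bin = levels(per_patient$bin)),
             on = .(week, bin)]
  tab[is.na(n), n := 0L]
  tab[, denom := sum(n), by = week]
  tab[, pct := round(100 * n / denom, 2)]
  data.table::setorder(tab, week, bin)
  list(per_patient = per_patient[], table = tab[])
}

#' Cumulative prednisolone-equivalent dose up to a day
#'
#' Sums the daily dose series over covered days at or before `up_to`
#' (pulse / high-dose days contribute 0, consistently with the dose
#' assessment), and assigns the nested case-control cumulative-dose bin.
#'
#' @param series output of [cs_daily_series()].
#' @param who data.table with `patient_id` and `up_to` (Date).
#' @param config an [itp_config()] object.
#' @return data.table: `patient_id`, `up_to`, `cum_mg`, `cum_bin`.
#' @export
cumulative_dose <- function(series, who, config = itp_config()) {
  who <- data.table::as.data.table(who)
  s <- series[who, on = .(patient_id, date <= up_to),
              .(cum_mg = sum(psl_mg, na.rm = TRUE),
                any_cov = sum(!is.na(covered))), by = .EACHI]
  out <- data.table::data.table(patient_id = who$patient_id,
                                up_to = who$up_to,
                                cum_mg = s$cum_mg, n_cov = s$any_cov)
  out[is.na(cum_mg), `:=`(cum_mg = 0, n_cov = 0L)]
  labs <- bin_labels(config$ncc_cumdose_bins_mg)
  out[, cum_bin := bin_value(cum_mg, config$ncc_cumdose_bins_mg)]
  # covered but zero-dose (all pulse) still counts as treated: put in lowest
  out[cum_mg == 0 & n_cov > 0L, cum_bin := factor(labs[2L], levels = labs)]
  out[, n_cov := NULL]
  out[]
}

#' CS duration (covered days) up to a day, with nested case-control bins
#' @inheritParams cumulative_dose
#' @return data.table: `patient_id`, `up_to`, `cs_days`, `dur_bin`.
#' @export
duration_at <- function(series, who, config = itp_config()) {
  who <- data.table::as.data.table(who)
  s <- series[who, on = .(patient_id, date <= up_to),
              .(cs_days = sum(!is.na(covered))), by = .EACHI]
  out <- data.table::data.table(patient_id = who$patient_id,
                                up_to = who$up_to, cs_days = s$cs_days)
  out[is.na(cs_days), cs_days := 0L]
  out[, dur_bin := bin_value(cs_days, config$ncc_duration_bins_days)]
  out[]
}

#' Time to CS withdrawal per CS-treated cohort patient
#'
#' CS is withdrawn when the interval from a prescription-run end date
#' (date + days_supplied) to the next CS prescription date is at least
#' `withdrawal_gap_days` (default 60), or when no CS is prescribed for at
#' least that many days from the last run end to the assessment end. The event
#' time is the qualifying end date minus the first CS date; follow-up is
#' capped at `followup_cap_withdrawal_days` (183 = 6 months) and at the
#' assessment end. The calendar era is assigned by the year of CS initiation.
#'
#' @param claims a `claims` object.
#' @param cohort the cohort table.
#' @param config an [itp_config()] object.
#' @return data.table: `patient_id`, `cs_start`, `time`, `event`, `year`,
#'   `era` (NA outside the configured era years).
#' @export
withdrawal_time <- function(claims, cohort, config = itp_config()) {
  rx <- claims$prescriptions[drug_class == "CS" &
                               patient_id %in% cohort$patient_id,
                             .(patient_id, date, days_supplied)]
  rx <- rx[cohort[, .(patient_id, entry_date, assessment_end)],
           on = "patient_id", nomatch = NULL]
  rx <- rx[date >= entry_date & date <= assessment_end]
  if (nrow(rx) == 0L) {
    return(data.table::data.table(
      patient_id = character(0), cs_start = as.Date(character(0)),
      time = numeric(0), event = logical(0), year = integer(0),
      era = character(0)))
  }
  data.table::setorder(rx, patient_id, date)
  rx[, end_excl := cummax(as.integer(date) + days_supplied),
     by = patient_id]
  rx[, next_date := data.table::shift(as.integer(date), -1L), by = patient_id]
  rx[, gap := ifelse(is.na(next_date),
                     as.integer(assessment_end) - end_excl,
                     next_date - end_excl)]
  gapmin <- config$withdrawal_gap_days
  out <- rx[, {
    cs0 <- as.integer(date[1L])
    cap <- min(config$followup_cap_withdrawal_days,
               as.integer(assessment_end[1L]) - cs0)
    hit <- which(gap >= gapmin)
    if (length(hit)) {
      t_ev <- end_excl[hit[1L]] - cs0
      if (t_ev <= cap) {
        list(cs_start = date[1L], time = as.numeric(t_ev), event = TRUE)
      } else {
        list(cs_start = date[1L], time = as.numeric(cap), event = FALSE)
      }
    } else {
      list(cs_start = date[1L], time = as.numeric(cap), event = FALSE)
    }
  }, by = patient_id]
  out[, year := year_of(cs_start)]
  out[, era := NA_character_]
  for (e in names(config$era_years)) {
    out[year %in% config$era_years[[e]], era := e]
  }
  out[]
}
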