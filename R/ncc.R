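# Nested case-control analysis: outcome ascertainment with look-back washout,
# risk-set (incidence-density) sampling with time-point matching on the
# at-risk clock, exposure coding at the index time, and matched-set
# conditional logistic regression for each adverse outcome.

#' Ascertain an outcome for the cohort
#'
#' The at-risk population for an outcome excludes patients carrying any of the
#' outcome's look-back exclusion codes (prevalent-disease washout) in the
#' look-back window. The event time is the first day strictly after cohort
#' entry on which a non-suspected diagnosis matches the outcome code set;
#' at-risk time ends at the end of observation.
#'
#' @param cohort the cohort table from [select_cohort()].
#' @param diagnoses the diagnoses table.
#' @param defn outcome definition: list with `codes` and `exclude_codes`.
#' @param config an [itp_config()] object.
#' @return data.table: `patient_id`, `event_time` (days since entry, NA if
#'   none), `atrisk_end` (days since entry), restricted to the at-risk
#'   population.
#' @export
ascertain_outcome <- function(cohort, diagnoses, defn,
                              config = itp_config()) {
  stopifnot(length(defn$codes) > 0L)
  dxn <- diagnoses[suspected == FALSE]
  base <- cohort[, .(patient_id, entry_date, lookback_start, obs_end_day)]
  if (length(defn$exclude_codes)) {
    ex <- dxn[code %in% defn$exclude_codes, .(patient_id, dx_date = date)]
    hits <- ex[base, on = .(patient_id, dx_date >= lookback_start,
                            dx_date < entry_date),
               .(k = sum(!is.na(x.dx_date))), by = .EACHI]$k
    base <- base[hits == 0L]
  }
  oc <- dxn[code %in% defn$codes, .(patient_id, dx_date = date)]
  hits_ev <- oc[base, on = "patient_id"][!is.na(dx_date) &
                                           dx_date > entry_date]
  first_ev <- if (nrow(hits_ev)) {
    hits_ev[, .(ev_date = min(dx_date)), by = patient_id]
  } else {
    data.table::data.table(patient_id = character(0),
                           ev_date = as.Date(character(0)))
  }
  out <- first_ev[base, on = "patient_id"]
  out[, event_time := as.numeric(ev_date - entry_date)]
  out[, atrisk_end := as.numeric(obs_end_day - entry_date)]
  out[!is.na(event_time) & event_time > atrisk_end, event_time := NA_real_]
  out[, .(patient_id, event_time, atrisk_end)]
}

#' Sample risk sets for a set of cases
#'
#' For each case at time `t` (days since entry), eligible controls are
#' patients at risk at `t` on their own at-risk clock: observed through `t`
#' and outcome-free before and at `t` (future cases are eligible and may be
#' sampled for several cases). Up to `ratio` controls are sampled without
#' replacement per case with the seeded RNG; cases with no eligible control
#' are dropped. The result is independent of the input row order.
#'
#' @param ascertained output of [ascertain_outcome()].
#' @param ratio maximum controls per case.
#' @param seed integer RNG seed.
#' @return data.table: `set_id`, `patient_id`, `is_case`, `event_time`;
#'   attribute `n_cases_dropped`.
#' @export
sample_risk_sets <- function(ascertained, ratio, seed) {
  if (ratio < 1L) stop("matching ratio must be >= 1", call. = FALSE)
  # force the input before seeding: evaluating the caller's expression may
  # itself consume RNG, which must not perturb the seeded sampling stream
  a <- data.table::copy(data.table::as.data.table(ascertained))
  set.seed(as.integer(seed))
  # eligibility horizon: a patient can serve as control at any t < event_time
  # (if a future case) and t <= atrisk_end
  a[, horizon := pmin(atrisk_end, ifelse(is.na(event_time), Inf,
                                         event_time - 0.5))]
  data.table::setorder(a, -horizon, patient_id)
  horizons <- a$horizon
  ids <- a$patient_id
  n_all <- length(horizons)
  hasc <- rev(horizons)  # ascending, for findInterval
  cases <- a[!is.na(event_time)][order(event_time, patient_id)]
  sets <- vector("list", nrow(cases))
  dropped <- 0L
  for (i in seq_len(nrow(cases))) {
    t <- cases$event_time[i]
    # first k of the desc-sorted vector have horizon >= t
    k <- n_all - findInterval(t - 1e-9, hasc)
    if (k == 0L) {
      dropped <- dropped + 1L
      next
    }
    m <- min(ratio, k)
    pick <- if (k == 1L) 1L else sample.int(k, m)
    sets[[i]] <- data.table::data.table(
      set_id = i,
      patient_id = c(cases$patient_id[i], ids[pick]),
      is_case = c(TRUE, rep(FALSE, m)),
      event_time = t)
  }
  out <- data.table::rbindlist(sets)
  if (nrow(out)) data.table::setattr(out, "n_cases_dropped", dropped)
  out
}

#' Code CS exposure of matched-set members at the index time
#'
#' Exposure is computed from each member's own cohort entry up to (and
#' including) day `event_time` on their at-risk clock: presence (any CS /
#' none; under `config$ncc_exposure = "current"`, CS coverage on the index
#' day itself), duration category, and cumulative prednisolone-equivalent
#' dose category, plus the regression covariates (gender, age at entry,
#' malignancy, pulmonary disease, liver disease).
#'
#' @param sets output of [sample_risk_sets()].
#' @param series output of [cs_daily_series()].
#' @param cohort the cohort table.
#' @param config an [itp_config()] object.
#' @return `sets` with columns `exposed`, `cs_days`, `dur_bin`, `cum_mg`,
#'   `cum_bin`, `gender`, `age`, `malignancy`, `pulmonary`, `liver`.
#' @export
code_exposure <- function(sets, series, cohort, config = itp_config()) {
  s <- data.table::copy(sets)
  s <- cohort[, .(patient_id, entry_date, gender, age = age_at_entry,
                  malignancy = cov_malignancy,
                  pulmonary = cov_pulmonary_disease,
                  liver = cov_liver_disease)][s, on = "patient_id"]
  # exposure window runs from entry to the day BEFORE the index day, so a
  # case whose event falls on day t counts t days of prior person-time
  s[, up_to := entry_date + event_time - 1L]
  who <- s[, .(patient_id, up_to)]
  dur <- duration_at(series, who, config)
  cum <- cumulative_dose(series, who, config)
  s[, cs_days := dur$cs_days]
  s[, dur_bin := dur$dur_bin]
  s[, cum_mg := cum$cum_mg]
  s[, cum_bin := cum$cum_bin]
  if (config$ncc_exposure == "current") {
    cur <- series[s[, .(patient_id, date = up_to)], on = .(patient_id, date),
                  nomatch = NA]
    s[, exposed := !is.na(cur$covered)]
  } else {
    s[, exposed := cs_days > 0L]
  }
  s[]
}

#' Matched-set conditional logistic regression for one exposure coding
#'
#' Builds the design matrix for the requested exposure coding (reference =
#' Untreated / no CS), optionally adds the five adjustment covariates, and
#' fits [clogit_fit()].
#'
#' @param coded output of [code_exposure()].
#' @param coding one of "presence", "duration", "cumdose".
#' @param adjusted add gender, age, malignancy, pulmonary and liver disease.
#' @param config an [itp_config()] object.
#' @return data.table with one row per non-reference exposure level: `level`,
#'   `n_cases`, `n_controls`, `or`, `ci_lower`, `ci_upper`, `p`, `model`.
#' @export
conditional_logistic <- function(coded, coding = "presence",
                                 adjusted = FALSE, config = itp_config()) {
  expo <- switch(coding,
                 presence = factor(ifelse(coded$exposed, "Yes", "No"),
                                   levels = c("No", "Yes")),
                 duration = coded$dur_bin,
                 cumdose = coded$cum_bin,
                 stop("unknown coding: ", coding, call. = FALSE))
  lv <- levels(expo)
  xe <- stats::model.matrix(~ expo)[, -1L, drop = FALSE]
  colnames(xe) <- sub("^expo", "", colnames(xe))
  x <- xe
  if (adjusted) {
    xa <- cbind(male = as.numeric(coded$gender == "male"),
                age = as.numeric(coded$age),
                malignancy = as.numeric(coded$malignancy),
                pulmonary = as.numeric(coded$pulmonary),
                liver = as.numeric(coded$liver))
    x <- cbind(xe, xa)
  }
  fit <- clogit_fit(coded$is_case, x, coded$set_id)
  lev_names <- colnames(xe)
  counts <- data.table::data.table(level = as.character(expo),
                                   is_case = coded$is_case)[
    , .(n_cases = sum(is_case), n_controls = sum(!is_case)), by = level]
  out <- data.table::data.table(
    level = lev_names,
    or = fit$or[seq_along(lev_names)],
    ci_lower = fit$ci_lower[seq_along(lev_names)],
    ci_upper = fit$ci_upper[seq_along(lev_names)],
    p = fit$p[seq_along(lev_names)],
    model = if (adjusted) "multivariate" else "univariate")
  out <- counts[out, on = "level"]
  out[, coding := coding]
  out[]
}

#' Run the nested case-control analysis for every configured outcome
#'
#' For each outcome definition: ascertain events in the at-risk population,
#' skip outcomes with fewer than `min_cases` matched cases (logged), sample
#' risk sets, code exposures, and fit univariate and multivariate conditional
#' logistic models for the three exposure codings. Sampling seeds are derived
#' deterministically per outcome from `seed`.
#'
#' @param claims a `claims` object.
#' @param cohort the cohort table.
#' @param series output of [cs_daily_series()].
#' @param config an [itp_config()] object.
#' @param seed integer base seed for risk-set sampling.
#' @return list: `incidence` (per-outcome at-risk N, cases, proportion),
#'   `results` (stacked regression results), `sets` (matched-set tables),
#'   `skipped` (outcomes skipped with reason).
#' @export
run_all_outcomes <- function(claims, cohort, series, config = itp_config(),
                             seed = config$rng_seed) {
  res <- list(); inc <- list(); skipped <- list(); all_sets <- list()
  oc_names <- names(config$outcomes)
  for (k in seq_along(oc_names)) {
    oc <- oc_names[k]
    asc <- ascertain_outcome(cohort, claims$diagnoses, config$outcomes[[oc]],
                             config)
    n_at_risk <- nrow(asc)
    n_cases <- sum(!is.na(asc$event_time))
    inc[[oc]] <- data.table::data.table(
      outcome = oc, n_at_risk = n_at_risk, n_cases = n_cases,
      incidence_pct = round(100 * n_cases / max(n_at_risk, 1L), 2))
    if (n_cases < config$min_cases) {
      skipped[[oc]] <- data.table::data.table(
        outcome = oc, reason = sprintf("insufficient cases (%d < %d)",
                                       n_cases, config$min_cases))
      message("skipping outcome '", oc, "': insufficient cases (",
              n_cases, ")")
      next
    }
    sets <- sample_risk_sets(asc, config$matching_ratio,
                             seed = as.integer(seed) + k)
    if (nrow(sets) == 0L) {
      skipped[[oc]] <- data.table::data.table(
        outcome = oc, reason = "no matchable cases")
      next
    }
    coded <- code_exposure(sets, series, cohort, config)
    all_sets[[oc]] <- coded
    for (coding in c("presence", "duration", "cumdose")) {
      for (adj in c(FALSE, TRUE)) {
        r <- tryCatch(
          conditional_logistic(coded, coding, adjusted = adj, config),
          error = function(e) {
            data.table::data.table(
              level = NA_character_, n_cases = NA_integer_,
              n_controls = NA_integer_, or = NA_real_, ci_lower = NA_real_,
              ci_upper = NA_real_, p = NA_real_,
              model = if (adj) "multivariate" else "univariate",
              coding = coding)
          })
        r[, outcome := oc]
        res[[paste(oc, coding, adj)]] <- r
      }
    }
  }
  list(incidence = data.table::rbindlist(inc),
       results = data.table::rbindlist(res, use.names = TRUE, fill = TRUE),
       sets = all_sets,
       skipped = data.table::rbindlist(skipped))
}
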