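# Synthetic administrative-claims generator. Emulates the structure the
# analysis assumes -- enrollment spans, monthly ITP diagnosis codes, dated CS /
# TPO-RA / rituximab prescriptions with dose and days supplied, splenectomy,
# look-back comorbidities, era-dependent treatment mix -- with known ground
# truth: a discrete-time (daily) logistic outcome hazard whose odds are
# multiplied by a known factor while the patient is CS-exposed, so the
# incidence-density-sampled conditional-logistic odds ratio has a known
# estimand.

#' Simulation parameters for the synthetic claims generator
#'
#' Defaults encode the marginal shapes of the source population: elderly ages
#' (median ~78, IQR ~68-84), ~51% female, ~50% of ITP patients treated, the
#' observed initial CS dose mix (mode at 20-40 mg/day prednisolone), a taper
#' that halves the dose every 2 weeks, withdrawal-time medians of 35 days for
#' CS starts before 2020 and 28 days from 2020 on, and eltrombopag uptake
#' rising by calendar year.
#'
#' @param n_patients number of subscribers to simulate.
#' @param span_start,span_end database span as "YYYY-MM" strings.
#' @param p_female probability of female gender.
#' @param age_shape,age_scale,age_min,age_max age at enrollment is
#'   `age_max - Gamma(shape, scale)`, truncated to `[age_min, age_max]`
#'   (right-skewed toward old age).
#' @param p_itp probability a subscriber ever carries an ITP diagnosis code.
#' @param p_suspected_only probability an ITP patient's codes are all
#'   suspected-only (excluded by cohort selection).
#' @param p_short_lookback probability the first ITP code falls less than the
#'   look-back span after enrollment start (excluded by cohort selection).
#' @param p_prevalent_cs probability of a CS prescription inside the look-back
#'   window (prevalent user, excluded).
#' @param p_treated_given_itp probability an eligible ITP patient receives any
#'   ITP treatment.
#' @param p_cs_first probability the first-line treatment includes CS (else a
#'   TPO-RA is started first).
#' @param initial_dose_mg,initial_dose_probs categorical initial prednisolone
#'   dose distribution (mg/day) for CS starters.
#' @param taper_schedule data.frame with columns `week`, `frac`: fraction of
#'   the initial dose prescribed from that week on (step function).
#' @param cs_duration_dist "lognormal" or "exponential" CS course length.
#' @param cs_duration_median_pre2020,cs_duration_median_2020on era-dependent
#'   median CS course length in days.
#' @param cs_duration_sdlog lognormal sd(log) of the course length.
#' @param script_days days supplied per CS prescription (last one trimmed).
#' @param p_pulse probability a CS starter receives methylprednisolone pulse
#'   therapy (500 mg/day x 3 days, injection) at the start.
#' @param p_readmin probability of a later second CS course.
#' @param readmin_gap_meanlog,readmin_gap_sdlog lognormal gap (days) between
#'   the end of the first and start of the second CS course.
#' @param p_epag_addon base probability of an eltrombopag add-on/switch after
#'   CS start (multiplied by `era_epag_multiplier`).
#' @param era_epag_multiplier named vector year -> multiplier on EPAG uptake.
#' @param p_romi,p_rtx,p_other_is,p_splenectomy probabilities of romiplostim,
#'   rituximab, other-immunosuppressant use and splenectomy among treated.
#' @param itp_active_meanlog,itp_active_sdlog lognormal active-disease span
#'   (days) over which monthly ITP codes are recorded.
#' @param p_inpatient_entry probability the entry diagnosis carries the
#'   inpatient flag.
#' @param p_pregnancy_itp probability (females) of a pregnancy-with-ITP coded
#'   month inside the assessment period.
#' @param comorbidity_prev named vector concept -> look-back prevalence.
#' @param outcome_h0 per-day baseline outcome hazard; scalar or named vector
#'   by outcome (unnamed/default element recycled).
#' @param true_or named vector outcome -> multiplicative odds effect of CS
#'   exposure on the daily outcome hazard.
#' @param exposure_type "ever" (exposed from first CS day on) or "current"
#'   (exposed on CS-covered days only) for the ground-truth hazard.
#' @param rng_seed integer seed used by [simulate_claims()] when no explicit
#'   seed is passed.
#' @return a `sim_params` object (validated named list).
#' @export
sim_params <- function(n_patients = 20000L,
                       span_start = "2014-04",
                       span_end = "2022-08",
                       p_female = 0.51,
                       age_shape = 3, age_scale = 8.7,
                       age_min = 20L, age_max = 101L,
                       p_itp = 0.85,
                       p_suspected_only = 0.04,
                       p_short_lookback = 0.06,
                       p_prevalent_cs = 0.04,
                       p_treated_given_itp = 0.5,
                       p_cs_first = 0.75,
                       initial_dose_mg = c(1.25, 3.75, 6.25, 8.75, 15, 30, 50, 70),
                       initial_dose_probs = c(56, 66, 56, 31, 142, 539, 249, 137) / 1276,
                       taper_schedule = data.frame(
                         week = c(0, 2, 4, 6, 8, 10),
                         frac = c(1, 0.5, 0.25, 0.125, 0.0625, 0.05)),
                       cs_duration_dist = "lognormal",
                       cs_duration_median_pre2020 = 35,
                       cs_duration_median_2020on = 28,
                       cs_duration_sdlog = 1.2,
                       script_days = 7L,
                       p_pulse = 0.03,
                       p_readmin = 0.30,
                       readmin_gap_meanlog = log(120),
                       readmin_gap_sdlog = 0.6,
                       p_epag_addon = 0.25,
                       era_epag_multiplier = c("2014" = 0.3, "2015" = 0.4,
                                               "2016" = 0.5, "2017" = 0.7,
                                               "2018" = 0.9, "2019" = 1.1,
                                               "2020" = 1.3, "2021" = 1.5,
                                               "2022" = 1.5),
                       p_romi = 0.05, p_rtx = 0.05, p_other_is = 0.06,
                       p_splenectomy = 0.01,
                       itp_active_meanlog = log(300), itp_active_sdlog = 0.8,
                       p_inpatient_entry = 0.24,
                       p_pregnancy_itp = 0.01,
                       comorbidity_prev = c(
                         diabetes = 0.356, malignancy = 0.226,
                         pulmonary_disease = 0.269, liver_disease = 0.224,
                         osteoporosis = 0.228, dyslipidemia = 0.431,
                         hypertension = 0.582, cataract = 0.213,
                         glaucoma = 0.132, infection = 0.224,
                         peptic_ulcer = 0.023, thromboembolism = 0.05,
                         depression = 0.071, insomnia = 0.272),
                       outcome_h0 = c(infection = 1e-3, default = 2.5e-4),
                       true_or = c(infection = 3, diabetes = 2, osteoporosis = 2,
                                   dyslipidemia = 2, hypertension = 2,
                                   peptic_ulcer = 2, psychosis = 2, cataract = 2,
                                   glaucoma = 2, thromboembolism = 2),
                       exposure_type = "ever",
                       rng_seed = 1L) {
  p <- as.list(environment())
  probs <- p[grep("^p_", names(p))]
  if (any(unlist(probs) < 0 | unlist(probs) > 1)) {
    stop("probabilities must be in [0, 1]", call. = FALSE)
  }
  if (any(diff(p$taper_schedule$frac) > 0)) {
    stop("taper fractions must be non-increasing", call. = FALSE)
  }
  if (any(p$true_or <= 0)) stop("true_or must be positive", call. = FALSE)
  if (!p$exposure_type %in% c("ever", "current")) {
    stop("exposure_type must be 'ever' or 'current'", call. = FALSE)
  }
  if (!p$cs_duration_dist %in% c("lognormal", "exponential")) {
    stop("cs_duration_dist must be 'lognormal' or 'exponential'", call. = FALSE)
  }
  structure(p, class = "sim_params")
}

h0_for <- function(outcome_h0, outcome) {
  if (length(outcome_h0) == 1L && is.null(names(outcome_h0))) {
    return(unname(outcome_h0))
  }
  if (outcome %in% names(outcome_h0)) return(unname(outcome_h0[outcome]))
  if ("default" %in% names(outcome_h0)) return(unname(outcome_h0["default"]))
  stop("no baseline hazard for outcome ", outcome, call. = FALSE)
}

taper_frac <- function(schedule, week) {
  idx <- findInterval(week, schedule$week)
  ifelse(idx < 1L, 1, schedule$frac[pmax(idx, 1L)])
}

#' Simulate synthetic claims tables with known ground truth
#'
#' Generates the four claims tables plus a ground-truth object recording each
#' patient's true exposure trajectory and outcome times. Outcomes follow a
#' discrete-time daily logistic hazard: on each at-risk day the event odds are
#' `odds0 * true_or[outcome]` if the patient is CS-exposed on that day (under
#' `exposure_type`), `odds0` otherwise, with `odds0 = h0 / (1 - h0)`. Identical
#' parameters and seed give byte-identical tables.
#'
#' @param params a [sim_params()] object.
#' @param seed integer RNG seed; defaults to `params$rng_seed`.
#' @return list with elements `claims` (a `claims` object) and `truth` (list:
#'   `patients` data.table, `outcomes` data.table, `true_or`, `exposure_type`).
#' @export
#' @examples
#' sim <- simulate_claims(sim_params(n_patients = 200), seed = 7)
#' sim$claims
simulate_claims <- function(params = sim_params(), seed = params$rng_seed) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(as.integer(seed))
  n <- as.integer(params$n_patients)
  empty <- function() {
    tabs <- lapply(CLAIMS_SCHEMA, function(cols) {
      dt <- data.table::as.data.table(
        stats::setNames(rep(list(character(0)), length(cols)), cols))
      dt
    })
    as_claims(tabs)
  }
  if (n == 0L) {
    return(list(claims = empty(),
                truth = list(patients = data.table::data.table(),
                             outcomes = data.table::data.table(),
                             true_or = params$true_or,
                             exposure_type = params$exposure_type)))
  }

  span0 <- month_start(params$span_start)
  span1 <- month_start(params$span_end)
  n_span_months <- length(seq(span0, span1, by = "month"))

  id <- sprintf("P%06d", seq_len(n))
  gender <- ifelse(stats::runif(n) < params$p_female, "female", "male")
  # age at cohort entry (baseline-table target), right-skewed toward old age
  age <- params$age_max -
    pmin(pmax(stats::rgamma(n, shape = params$age_shape,
                            scale = params$age_scale), 0),
         params$age_max - params$age_min)
  age <- as.integer(round(age))
  # enroll early in the span so most patients have full look-back room
  obs_start <- add_months(span0, sample(0:17, n, replace = TRUE,
                                        prob = 18:1))
  disenroll <- stats::runif(n) < 0.10
  obs_end <- rep(span1, n)
  late <- add_months(obs_start, 30L +
                       sample.int(36L, n, replace = TRUE))
  obs_end[disenroll] <- pmin(late[disenroll], span1)
  is_itp <- stats::runif(n) < params$p_itp
  # entry: first ITP diagnosis date
  lb_months <- 6L
  lo <- add_months(obs_start, lb_months)
  hi <- month_end(obs_end) - 90L
  entry <- as.Date(ifelse(hi > lo, lo + floor(stats::runif(n) *
                                                as.numeric(hi - lo + 1L)), lo),
                   origin = "1970-01-01")
  short_lb <- is_itp & stats::runif(n) < params$p_short_lookback
  entry[short_lb] <- month_start(obs_start[short_lb]) +
    sample.int(120L, sum(short_lb), replace = TRUE)
  entry <- pmin(entry, month_end(obs_end))
  birth_year <- year_of(entry) - age
  patients <- data.table::data.table(
    patient_id = id, gender = gender, birth_year = birth_year,
    observation_start = ym(obs_start), observation_end = ym(obs_end))
  suspected_only <- is_itp & stats::runif(n) < params$p_suspected_only
  prevalent_cs <- is_itp & stats::runif(n) < params$p_prevalent_cs

  active_days <- pmax(round(stats::rlnorm(n, params$itp_active_meanlog,
                                          params$itp_active_sdlog)), 30)
  assess_end <- pmin(entry + active_days, month_end(obs_end))
  obs_end_day <- month_end(obs_end)

  eligible <- is_itp & !suspected_only & !short_lb & !prevalent_cs &
    (year_of(entry) - birth_year) >= 20L
  treated <- eligible & stats::runif(n) < params$p_treated_given_itp
  cs_first_line <- treated & stats::runif(n) < params$p_cs_first
  # TPO-first patients may still get CS later; keep them CS-free for truth
  # simplicity: exposure truth is driven by cs_start below.

  ## ---- CS courses -------------------------------------------------------
  cs_idx <- which(cs_first_line)
  n_cs <- length(cs_idx)
  cs_start <- rep(as.Date(NA), n)
  cs_dur <- rep(NA_real_, n)
  initial_dose <- rep(NA_real_, n)
  if (n_cs) {
    cs_start[cs_idx] <- entry[cs_idx] + sample(0:7, n_cs, replace = TRUE)
    med <- ifelse(year_of(cs_start[cs_idx]) >= 2020,
                  params$cs_duration_median_2020on,
                  params$cs_duration_median_pre2020)
    if (params$cs_duration_dist == "lognormal") {
      d <- stats::rlnorm(n_cs, log(med), params$cs_duration_sdlog)
    } else {
      d <- stats::rexp(n_cs, rate = log(2) / med)
    }
    cs_dur[cs_idx] <- pmax(1, round(d))
    initial_dose[cs_idx] <- params$initial_dose_mg[
      sample.int(length(params$initial_dose_mg), n_cs, replace = TRUE,
                 prob = params$initial_dose_probs)]
  }
  # clip course to assessment period
  cs_dur <- pmin(cs_dur, as.numeric(assess_end - cs_start) + 1)
  cs_dur <- pmax(cs_dur, 1)

  rx_list <- list()
  # oral tapered prednisolone scripts
  if (n_cs) {
    sd_ <- as.integer(params$script_days)
    nscr <- ceiling(cs_dur[cs_idx] / sd_)
    pid <- rep(id[cs_idx], nscr)
    k <- sequence(nscr) - 1L
    start0 <- rep(cs_start[cs_idx], nscr)
    dur0 <- rep(cs_dur[cs_idx], nscr)
    dose0 <- rep(initial_dose[cs_idx], nscr)
    offs <- k * sd_
    supplied <- pmin(sd_, dur0 - offs)
    week <- offs %/% 7L
    dose <- round(dose0 * taper_frac(params$taper_schedule, week), 2)
    rx_list$cs <- data.table::data.table(
      patient_id = pid, date = start0 + offs, drug_class = "CS",
      drug_name = "prednisolone", route = "oral",
      daily_dose_mg = dose, days_supplied = as.integer(supplied))
  }
  # methylprednisolone pulse at course start for a small fraction
  pulse_idx <- cs_idx[stats::runif(n_cs) < params$p_pulse]
  if (length(pulse_idx)) {
    rx_list$pulse <- data.table::data.table(
      patient_id = id[pulse_idx], date = cs_start[pulse_idx],
      drug_class = "CS", drug_name = "methylprednisolone",
      route = "injection", daily_dose_mg = 500,
      days_supplied = 3L)
  }
  # second CS course (re-administration)
  cs_end1 <- cs_start + cs_dur - 1L
  re_idx <- cs_idx[stats::runif(n_cs) < params$p_readmin]
  if (length(re_idx)) {
    gap <- pmax(round(stats::rlnorm(length(re_idx), params$readmin_gap_meanlog,
                                    params$readmin_gap_sdlog)), 7)
    st2 <- cs_end1[re_idx] + 1L + gap
    d2 <- pmax(1, round(stats::rlnorm(length(re_idx), log(21), 0.8)))
    ok <- st2 <= assess_end[re_idx]
    re_idx <- re_idx[ok]; st2 <- st2[ok]; d2 <- d2[ok]
    d2 <- pmin(d2, as.numeric(assess_end[re_idx] - st2) + 1)
    if (length(re_idx)) {
      nscr <- ceiling(d2 / 7)
      k <- sequence(nscr) - 1L
      supplied <- pmin(7, rep(d2, nscr) - k * 7)
      rx_list$cs2 <- data.table::data.table(
        patient_id = rep(id[re_idx], nscr), date = rep(st2, nscr) + k * 7L,
        drug_class = "CS", drug_name = "prednisolone", route = "oral",
        daily_dose_mg = rep(pmax(round(initial_dose[re_idx] / 3, 2), 1), nscr),
        days_supplied = as.integer(supplied))
    }
  }
  # prevalent users: CS inside the look-back window
  prev_idx <- which(prevalent_cs)
  if (length(prev_idx)) {
    rx_list$prev <- data.table::data.table(
      patient_id = id[prev_idx],
      date = entry[prev_idx] - sample(10:120, length(prev_idx), replace = TRUE),
      drug_class = "CS", drug_name = "prednisolone", route = "oral",
      daily_dose_mg = 10, days_supplied = 14L)
  }

  ## ---- second-line / first-line TPO-RAs, RTX, others --------------------
  emit_scripts <- function(who, start, dur, class, name, route, dose, every,
                           supplied_each) {
    ok <- !is.na(start) & start <= assess_end[who]
    who <- who[ok]; start <- start[ok]; dur <- dur[ok]
    if (!length(who)) return(NULL)
    dur <- pmin(dur, as.numeric(assess_end[who] - start) + 1)
    nscr <- pmax(1L, ceiling(dur / every))
    k <- sequence(nscr) - 1L
    data.table::data.table(
      patient_id = rep(id[who], nscr), date = rep(start, nscr) + k * every,
      drug_class = class, drug_name = name, route = route,
      daily_dose_mg = dose, days_supplied = supplied_each)
  }
  era_mult <- function(dates) {
    m <- params$era_epag_multiplier[as.character(year_of(dates))]
    m[is.na(m)] <- 1
    unname(m)
  }
  tpo_first <- which(treated & !cs_first_line)
  if (length(tpo_first)) {
    use_romi <- stats::runif(length(tpo_first)) < 0.1
    st <- entry[tpo_first] + sample(0:7, length(tpo_first), replace = TRUE)
    du <- pmax(30, round(stats::rlnorm(length(tpo_first), log(240), 0.8)))
    rx_list$tpo1e <- emit_scripts(tpo_first[!use_romi], st[!use_romi],
                                  du[!use_romi], "EPAG", "eltrombopag",
                                  "oral", 25, 30L, 30L)
    rx_list$tpo1r <- emit_scripts(tpo_first[use_romi], st[use_romi],
                                  du[use_romi], "ROMI", "romiplostim",
                                  "injection", 250, 7L, 7L)
  }
  if (n_cs) {
    p_ep <- pmin(params$p_epag_addon * era_mult(cs_start[cs_idx]), 0.9)
    ep_idx <- cs_idx[stats::runif(n_cs) < p_ep]
    if (length(ep_idx)) {
      st <- cs_start[ep_idx] +
        round(stats::runif(length(ep_idx), 14, cs_dur[ep_idx] + 30))
      du <- pmax(30, round(stats::rlnorm(length(ep_idx), log(240), 0.8)))
      rx_list$epag <- emit_scripts(ep_idx, st, du, "EPAG", "eltrombopag",
                                   "oral", 25, 30L, 30L)
    }
    romi_idx <- cs_idx[stats::runif(n_cs) < params$p_romi]
    if (length(romi_idx)) {
      st <- cs_start[romi_idx] +
        round(stats::runif(length(romi_idx), 30, cs_dur[romi_idx] + 90))
      du <- pmax(28, round(stats::rlnorm(length(romi_idx), log(120), 0.6)))
      rx_list$romi <- emit_scripts(romi_idx, st, du, "ROMI", "romiplostim",
                                   "injection", 250, 7L, 7L)
    }
    rtx_idx <- cs_idx[stats::runif(n_cs) < params$p_rtx]
    if (length(rtx_idx)) {
      st <- cs_start[rtx_idx] +
        round(stats::runif(length(rtx_idx), 30, cs_dur[rtx_idx] + 120))
      rx_list$rtx <- emit_scripts(rtx_idx, st, rep(22, length(rtx_idx)),
                                  "RTX", "rituximab", "injection", 375, 7L, 1L)
    }
    ois_idx <- cs_idx[stats::runif(n_cs) < params$p_other_is]
    if (length(ois_idx)) {
      st <- cs_start[ois_idx] +
        round(stats::runif(length(ois_idx), 0, cs_dur[ois_idx] + 60))
      du <- pmax(30, round(stats::rlnorm(length(ois_idx), log(120), 0.7)))
      rx_list$ois <- emit_scripts(ois_idx, st, du, "OTHER_IS", "cyclosporine",
                                  "oral", 100, 30L, 30L)
    }
  }
  prescriptions <- data.table::rbindlist(rx_list, use.names = TRUE)
  if (nrow(prescriptions)) {
    data.table::setorder(prescriptions, patient_id, drug_class, date, drug_name)
  }

  ## ---- procedures -------------------------------------------------------
  spl_idx <- which(treated & stats::runif(n) < params$p_splenectomy)
  procedures <- data.table::data.table(
    patient_id = id[spl_idx],
    date = entry[spl_idx] + sample(60:400, length(spl_idx), replace = TRUE),
    procedure = rep("splenectomy", length(spl_idx)))
  procedures <- procedures[date <= obs_end_day[spl_idx]]

  ## ---- diagnoses --------------------------------------------------------
  dx_list <- list()
  itp_idx <- which(is_itp)
  if (length(itp_idx)) {
    m0 <- month_start(entry[itp_idx])
    m1 <- month_start(assess_end[itp_idx])
    mnum <- function(d) year_of(d) * 12L + as.integer(format(d, "%m"))
    nm <- pmax(1L, mnum(m1) - mnum(m0) + 1L)
    pid <- rep(id[itp_idx], nm)
    k <- sequence(nm) - 1L
    mdate <- add_months(rep(m0, nm), k)
    dday <- as.Date(ifelse(k == 0L, rep(entry[itp_idx], nm), mdate + 14L),
                    origin = "1970-01-01")
    dx_list$itp <- data.table::data.table(
      patient_id = pid, date = dday, code = "D69.3",
      suspected = rep(suspected_only[itp_idx], nm),
      inpatient = k == 0L &
        rep(stats::runif(length(itp_idx)) < params$p_inpatient_entry, nm))
  }
  # look-back comorbidities
  for (co in names(params$comorbidity_prev)) {
    has <- which(is_itp & stats::runif(n) < params$comorbidity_prev[[co]])
    if (!length(has)) next
    dx_list[[co]] <- data.table::data.table(
      patient_id = id[has],
      date = entry[has] - sample(1:180, length(has), replace = TRUE),
      code = default_code_lists()[[co]],
      suspected = FALSE, inpatient = FALSE)
  }
  # pregnancy-with-ITP months
  preg <- which(is_itp & gender == "female" &
                  stats::runif(n) < params$p_pregnancy_itp)
  if (length(preg)) {
    pdate <- entry[preg] + sample(30:200, length(preg), replace = TRUE)
    keep <- pdate <= assess_end[preg]
    dx_list$preg <- data.table::data.table(
      patient_id = id[preg][keep], date = pdate[keep], code = "O99.1",
      suspected = FALSE, inpatient = FALSE)
  }
  # anodyne code for non-ITP subscribers so every patient has a claim
  non_itp <- which(!is_itp)
  if (length(non_itp)) {
    dx_list$z <- data.table::data.table(
      patient_id = id[non_itp],
      date = month_start(obs_start[non_itp]) + 60L,
      code = "Z00", suspected = FALSE, inpatient = FALSE)
  }

  ## ---- outcomes: discrete-time logistic hazard --------------------------
  # exposure offset e: first at-risk day index (1-based; day d is calendar
  # date entry + d) on which the patient counts as CS-exposed under "ever"
  # coding. Exposure in the downstream analysis is coded strictly before the
  # index day, so the first exposed hazard day is the day AFTER cs_start.
  tmax <- pmax(as.numeric(obs_end_day - entry), 0)
  e_off <- ifelse(is.na(cs_start), Inf, as.numeric(cs_start - entry) + 1)
  truth_outcomes <- list()
  for (oc in names(params$true_or)) {
    h0 <- h0_for(params$outcome_h0, oc)
    or <- params$true_or[[oc]]
    p1 <- stats::plogis(stats::qlogis(h0) + log(or))
    if (params$exposure_type == "ever") {
      # segment 1: days 1 .. min(e-1, tmax) at h0; segment 2: rest at p1
      t1 <- stats::rgeom(n, h0) + 1
      len1 <- pmin(e_off - 1, tmax)
      ev1 <- t1 <= len1
      t2 <- stats::rgeom(n, p1) + 1
      ev2 <- !ev1 & (pmax(len1, 0) + t2) <= tmax & is.finite(e_off)
      # untreated patients: only segment 1 applies over full tmax
      ev1u <- !is.finite(e_off) & t1 <= tmax
      day <- rep(NA_real_, n)
      day[ev1 | ev1u] <- t1[ev1 | ev1u]
      day[ev2] <- pmax(len1[ev2], 0) + t2[ev2]
    } else {
      day <- simulate_current_exposure_outcome(n, h0, p1, cs_start, entry,
                                               cs_dur, tmax)
    }
    hit <- which(!is.na(day) & day >= 1)
    if (length(hit)) {
      truth_outcomes[[oc]] <- data.table::data.table(
        patient_id = id[hit], outcome = oc, day = day[hit],
        date = entry[hit] + day[hit])
    }
  }
  truth_outcomes <- data.table::rbindlist(truth_outcomes)
  if (nrow(truth_outcomes)) {
    # outcome diagnoses only make sense for ITP patients under follow-up
    oc_dx <- truth_outcomes[patient_id %in% id[is_itp]]
    codes <- unlist(lapply(default_outcome_definitions(), `[[`, "codes"))
    dx_list$outcomes <- data.table::data.table(
      patient_id = oc_dx$patient_id, date = oc_dx$date,
      code = unname(codes[oc_dx$outcome]),
      suspected = FALSE, inpatient = FALSE)
  }

  diagnoses <- data.table::rbindlist(dx_list, use.names = TRUE)
  data.table::setorder(diagnoses, patient_id, date, code)
  # keep diagnoses inside each patient's observation window
  win <- data.table::data.table(
    patient_id = id, w0 = month_start(obs_start), w1 = obs_end_day)
  diagnoses <- win[diagnoses, on = "patient_id"][date >= w0 & date <= w1]
  diagnoses[, c("w0", "w1") := NULL]
  data.table::setcolorder(diagnoses, CLAIMS_SCHEMA$diagnoses)
  if (nrow(prescriptions)) {
    prescriptions <- win[prescriptions, on = "patient_id"][date <= w1]
    prescriptions[, c("w0", "w1") := NULL]
    data.table::setcolorder(prescriptions, CLAIMS_SCHEMA$prescriptions)
  } else {
    prescriptions <- data.table::data.table(
      patient_id = character(0), date = as.Date(character(0)),
      drug_class = character(0), drug_name = character(0),
      route = character(0), daily_dose_mg = numeric(0),
      days_supplied = integer(0))
  }
  if (!nrow(procedures)) {
    procedures <- data.table::data.table(
      patient_id = character(0), date = as.Date(character(0)),
      procedure = character(0))
  }

  truth_patients <- data.table::data.table(
    patient_id = id, itp = is_itp, eligible = eligible, treated = treated,
    cs_user = cs_first_line, entry = entry, assess_end = assess_end,
    obs_end_day = obs_end_day, cs_start = cs_start, cs_course_days = cs_dur,
    initial_dose_mg = initial_dose)

  claims <- as_claims(list(patients = patients, diagnoses = diagnoses,
                           prescriptions = prescriptions,
                           procedures = procedures))
  list(claims = validate_claims(claims),
       truth = list(patients = truth_patients, outcomes = truth_outcomes,
                    true_or = params$true_or,
                    exposure_type = params$exposure_type))
}

# "current" exposure: hazard elevated only on CS-covered days of the first
# course (plus none after). Three segments: pre-CS, on-CS, post-CS.
simulate_current_exposure_outcome <- function(n, h0, p1, cs_start, entry,
                                              cs_dur, tmax) {
  e <- ifelse(is.na(cs_start), Inf, as.numeric(cs_start - entry) + 1)
  len1 <- pmin(e - 1, tmax)
  len2 <- pmin(ifelse(is.finite(e), cs_dur, 0), pmax(tmax - pmax(len1, 0), 0))
  t1 <- stats::rgeom(n, h0) + 1
  t2 <- stats::rgeom(n, p1) + 1
  t3 <- stats::rgeom(n, h0) + 1
  day <- rep(NA_real_, n)
  ev1 <- t1 <= len1 | (!is.finite(e) & t1 <= tmax)
  day[ev1] <- t1[ev1]
  ev2 <- !ev1 & is.finite(e) & t2 <= len2
  day[ev2] <- pmax(len1[ev2], 0) + t2[ev2]
  ev3 <- !ev1 & !ev2 & is.finite(e) &
    (pmax(len1, 0) + len2 + t3) <= tmax
  day[ev3] <- pmax(len1[ev3], 0) + len2[ev3] + t3[ev3]
  day
}
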