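# Analysis configuration. Every tunable the source study leaves to supplements
# (code lists, gap periods, equivalence factors, bins, windows) lives here so
# that the pipeline is auditable and re-parameterisable. Code lists below are a
# synthetic ICD-10-like dialect matching the bundled claims generator; users
# with real claims must supply their own lists.

#' Build an analysis configuration
#'
#' Returns the full set of analysis constants with documented defaults:
#' a 6-month look-back, drug-class gap periods for episode merging, the
#' 60-day withdrawal rule with a 6-month (183-day) follow-up cap,
#' prednisolone (PSL) equivalence factors from the standard glucocorticoid
#' equivalence table (PSL 5 mg = methylprednisolone 4 mg = dexamethasone /
#' betamethasone 0.75 mg = hydrocortisone 20 mg), the descriptive duration
#' and weekly-dose bins, the nested case-control duration / cumulative-dose
#' bins, a 1:5 maximum matching ratio, and the week grid for the dose table
#' (initial week, every 2 weeks to week 20, then 24, 28, 52, 104, 156).
#'
#' @param ... named overrides for any default element.
#' @return an object of class `itp_config` (a validated named list).
#' @export
#' @examples
#' cfg <- itp_config(matching_ratio = 3)
#' cfg$withdrawal_gap_days
itp_config <- function(...) {
  cfg <- list(
    lookback_months = 6L,
    gap_days_by_class = c(CS = 30L, EPAG = 30L, ROMI = 28L, RTX = 90L,
                          OTHER_IS = 30L),
    injection_classes = c("ROMI", "RTX"),
    withdrawal_gap_days = 60L,
    followup_cap_withdrawal_days = 183L,
    psl_equivalence = c(prednisolone = 1, methylprednisolone = 1.25,
                        dexamethasone = 20 / 3, betamethasone = 20 / 3,
                        hydrocortisone = 0.25),
    # methylprednisolone pulse: 500-1000 mg/day for exactly 3 consecutive
    # days, injection route only; high-dose dexamethasone: 20-40 mg/day
    # (native dexamethasone mg) for exactly 4 consecutive days, any route.
    pulse_drug = "methylprednisolone",
    pulse_dose_range_mg = c(500, 1000),
    pulse_run_days = 3L,
    hdd_drug = "dexamethasone",
    hdd_dose_range_mg = c(20, 40),
    hdd_run_days = 4L,
    dose_bins_mg_per_day = c(2.5, 5, 7.5, 10, 20, 40, 60),
    duration_bins_days = c(60L, 90L, 180L),
    ncc_duration_bins_days = c(15L, 60L),
    ncc_cumdose_bins_mg = c(500, 1500),
    week_grid = c(0L, seq(2L, 20L, 2L), 24L, 28L, 52L, 104L, 156L),
    matching_ratio = 5L,
    min_cases = 10L,
    min_pattern_n = 5L,
    max_switches = 5L,
    combo_window_days = 14L,
    splenectomy_state_days = 90L,
    rtx_course_gap_days = 90L,
    era_years = list("2015-2019" = 2015:2019, "2020-2021" = 2020:2021),
    yearly_count_years = 2015:2021,
    min_age = 20L,
    ncc_exposure = "ever",     # "ever" or "current" CS before event time
    median_ci_method = "loglog",
    code_lists = default_code_lists(),
    outcomes = default_outcome_definitions(),
    rng_seed = 20140401L
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(cfg))
    if (length(bad)) {
      stop("unknown config field(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    cfg[names(dots)] <- dots
  }
  validate_config(structure(cfg, class = "itp_config"))
}

#' Default diagnosis code lists (synthetic dialect)
#'
#' Concept -> code-set map used by cohort selection and baseline covariates.
#' These codes are the dialect emitted by [simulate_claims()]; they are
#' placeholders, not a clinically validated code list.
#' @return named list of character vectors.
#' @export
default_code_lists <- function() {
  list(
    itp            = "D69.3",
    pregnancy_itp  = "O99.1",
    cohort_exclusions = character(0),  # e.g. secondary ITP codes
    diabetes       = "E11",
    malignancy     = "C80",
    pulmonary_disease = "J44",
    liver_disease  = "K76",
    osteoporosis   = "M80",
    dyslipidemia   = "E78",
    hypertension   = "I10",
    cataract       = "H25",
    glaucoma       = "H40",
    infection      = "A49",
    peptic_ulcer   = "K27",
    psychosis      = "F06",
    thromboembolism = "I74",
    depression     = "F32",
    insomnia       = "G47"
  )
}

#' Default adverse-outcome definitions for the nested case-control analysis
#'
#' Each outcome is defined by a diagnosis code set and a look-back exclusion
#' code set (prevalent-disease washout): a patient carrying an exclusion code
#' in the look-back window is removed from that outcome's at-risk population.
#' Definitions are diagnosis-code-only placeholders.
#' @return named list; each element has `codes` and `exclude_codes`.
#' @export
default_outcome_definitions <- function() {
  concepts <- c("infection", "diabetes", "osteoporosis", "dyslipidemia",
                "hypertension", "peptic_ulcer", "psychosis", "cataract",
                "glaucoma", "thromboembolism")
  cl <- default_code_lists()
  out <- lapply(concepts, function(co) {
    list(codes = cl[[co]], exclude_codes = cl[[co]])
  })
  names(out) <- concepts
  out
}

validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "itp_config"))
  if (cfg$matching_ratio < 1L) {
    stop("matching_ratio must be >= 1", call. = FALSE)
  }
  for (nm in c("dose_bins_mg_per_day", "duration_bins_days",
               "ncc_duration_bins_days", "ncc_cumdose_bins_mg", "week_grid")) {
    v <- cfg[[nm]]
    if (length(v) > 1L && any(diff(v) <= 0)) {
      stop(nm, " cut points must be strictly increasing", call. = FALSE)
    }
  }
  if (any(cfg$psl_equivalence <= 0)) {
    stop("psl_equivalence factors must be positive", call. = FALSE)
  }
  if (!cfg$ncc_exposure %in% c("ever", "current")) {
    stop("ncc_exposure must be 'ever' or 'current'", call. = FALSE)
  }
  if (length(cfg$code_lists$itp) == 0L) {
    stop("configuration error: ITP code list is empty", call. = FALSE)
  }
  cfg
}

#' Read an analysis configuration from a YAML file
#'
#' Elements present in the file override the defaults of [itp_config()];
#' absent elements keep their defaults.
#' @param path YAML file path.
#' @return `itp_config` object.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  for (nm in c("gap_days_by_class", "psl_equivalence")) {
    if (!is.null(raw[[nm]])) raw[[nm]] <- unlist(raw[[nm]])
  }
  do.call(itp_config, raw)
}

#' Write an analysis configuration to YAML
#' @param cfg `itp_config` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  out <- unclass(cfg)
  # named atomic vectors lose names as YAML sequences; write them as maps
  for (nm in c("gap_days_by_class", "psl_equivalence")) {
    out[[nm]] <- as.list(out[[nm]])
  }
  yaml::write_yaml(out, path)
  invisible(path)
}
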