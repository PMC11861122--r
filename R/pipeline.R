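# End-to-end pipeline orchestration with cached stage outputs, a run
# manifest (config hash, seed, file digests), and a small CLI front end.

STAGES <- c("simulate", "cohort", "exposure", "patterns", "km", "ncc")

stage_deps <- list(simulate = character(0),
                   cohort = "simulate",
                   exposure = "cohort",
                   patterns = "exposure",
                   km = "exposure",
                   ncc = "exposure")

#' Run pipeline stages in dependency order
#'
#' Stages: `simulate` (synthetic claims; skipped when `claims_dir` points at
#' existing input), `cohort`, `exposure`, `patterns`, `km`, `ncc`. Each stage
#' writes its outputs under `out_dir` and later stages reuse files already
#' present there, so stages can be re-run incrementally. A `manifest.json`
#' with the seed, config hash and per-file MD5 digests is written at the end;
#' identical config + seed + inputs reproduce identical digests.
#'
#' @param out_dir output directory.
#' @param stages character vector of stages to run (dependencies must have
#'   run before, in this call or a previous one).
#' @param config an [itp_config()] object (or path to a YAML config).
#' @param sim a [sim_params()] object for the simulate stage.
#' @param claims_dir optional directory with existing claims CSVs (replaces
#'   the simulate stage).
#' @param seed integer seed for simulation and risk-set sampling.
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(out_dir, stages = STAGES, config = itp_config(),
                         sim = sim_params(n_patients = 2000L),
                         claims_dir = NULL, seed = 1L) {
  if (is.character(config)) config <- read_config(config)
  stages <- match.arg(stages, STAGES, several.ok = TRUE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  pth <- function(...) file.path(out_dir, ...)
  have <- function(f) file.exists(pth(f))
  need <- function(stage, f) {
    if (!have(f)) {
      stop("dependency error: stage '", stage, "' requires output '", f,
           "' (run its upstream stage first)", call. = FALSE)
    }
  }
  log_msg <- function(...) message("[itpclaims] ", ...)

  claims <- NULL
  get_claims <- function(stage) {
    if (!is.null(claims)) return(claims)
    src <- if (!is.null(claims_dir)) claims_dir else pth("claims")
    if (!dir.exists(src)) {
      stop("dependency error: stage '", stage,
           "' requires claims (run 'simulate' or pass claims_dir)",
           call. = FALSE)
    }
    claims <<- read_claims(src)
    claims
  }

  if ("simulate" %in% stages) {
    res <- simulate_claims(sim, seed = seed)
    claims <- res$claims
    write_claims(claims, pth("claims"))
    truth <- res$truth
    jsonlite::write_json(
      list(true_or = as.list(truth$true_or),
           exposure_type = truth$exposure_type,
           n_patients = nrow(truth$patients)),
      pth("ground_truth.json"), auto_unbox = TRUE, digits = NA)
    write_results(truth$patients, pth("truth_patients.csv"))
    write_results(truth$outcomes, pth("truth_outcomes.csv"))
    log_msg("simulate: ", nrow(claims$patients), " patients, ",
            nrow(claims$prescriptions), " prescriptions")
  }

  cohort <- NULL
  load_cohort <- function(stage) {
    if (!is.null(cohort)) return(cohort)
    need(stage, "cohort.csv")
    co <- read_results(pth("cohort.csv"))
    co[, `:=`(entry_date = as.Date(entry_date),
              lookback_start = as.Date(lookback_start),
              assessment_end = as.Date(assessment_end),
              obs_end_day = as.Date(obs_end_day))]
    co[, excluded_months := lapply(
      strsplit(ifelse(is.na(excluded_months), "", excluded_months), ";"),
      function(x) x[nzchar(x)])]
    cohort <<- co
    co
  }

  if ("cohort" %in% stages) {
    sel <- select_cohort(get_claims("cohort"), config)
    cohort <- sel$cohort
    flat <- data.table::copy(cohort)
    flat[, excluded_months := vapply(excluded_months, paste, "",
                                     collapse = ";")]
    write_results(flat, pth("cohort.csv"))
    write_results(sel$exclusions, pth("exclusion_flow.csv"))
    write_results(baseline_table(cohort), pth("baseline_table.csv"))
    log_msg("cohort: ", nrow(cohort), " selected of ",
            sel$exclusions$n_remaining[1L])
  }

  series <- NULL
  if ("exposure" %in% stages) {
    co <- load_cohort("exposure")
    cl <- get_claims("exposure")
    series <- cs_daily_series(cl, co, config)
    write_results(series, pth("daily_dose_series.csv"))
    eps <- build_episodes(cl$prescriptions[patient_id %in% co$patient_id],
                          config)
    write_results(eps, pth("episodes.csv"))
    dur <- cs_duration(series, co, config)
    write_results(dur, pth("duration.csv"))
    dur_tab <- dur[, .(n = .N), by = duration_bin][
      , pct := round(100 * n / sum(n), 2)][order(duration_bin)]
    write_results(dur_tab, pth("duration_table.csv"))
    grid <- weekly_dose_grid(cl, series, co, config)
    write_results(grid$table, pth("dose_grid.csv"))
    wd <- withdrawal_time(cl, co, config)
    write_results(wd, pth("withdrawal.csv"))
    log_msg("exposure: ", nrow(eps), " episodes, ",
            sum(dur$cs_days > 0), " CS-treated patients")
  }

  load_series <- function(stage) {
    if (!is.null(series)) return(series)
    need(stage, "daily_dose_series.csv")
    s <- read_results(pth("daily_dose_series.csv"))
    s[, date := as.Date(date)]
    series <<- s
    s
  }

  if ("patterns" %in% stages) {
    co <- load_cohort("patterns")
    cl <- get_claims("patterns")
    eps <- build_episodes(cl$prescriptions[patient_id %in% co$patient_id],
                          config)
    yearly <- yearly_modality_counts(cl, co, config)
    write_results(yearly, pth("yearly_counts.csv"))
    st <- derive_states(eps, cl$procedures, config)
    sw <- switch_sequence(st, config)
    write_results(sw$flows, pth("flows.csv"))
    ln <- derive_lines(eps, cl$procedures, config)
    write_results(ln$table, pth("lines.csv"))
    sankey_export(sw$flows, pth("sankey.json"))
    log_msg("patterns: ", nrow(st), " states, ",
            max(ln$lines$line_index), " max line")
  }

  if ("km" %in% stages) {
    need("km", "withdrawal.csv")
    wd <- read_results(pth("withdrawal.csv"))
    wd[, cs_start := as.Date(cs_start)]
    ana <- withdrawal_analysis(wd, config)
    curves <- data.table::rbindlist(lapply(names(ana$fits), function(e) {
      cbind(era = e, ana$fits[[e]]$curve)
    }))
    write_results(curves, pth("km_curves.csv"))
    summ <- list(
      medians = lapply(ana$fits, function(f) {
        list(median = f$median, ci = as.list(f$median_ci), n = f$n,
             events = f$n_events)
      }),
      event_only = ana$event_only,
      surv_at = ana$surv_at,
      logrank = if (!is.null(ana$logrank)) {
        list(chi_square = ana$logrank$chi_square, p = ana$logrank$p)
      })
    jsonlite::write_json(summ, pth("km_summary.json"), auto_unbox = TRUE,
                         digits = NA, dataframe = "rows", na = "null")
    log_msg("km: ", length(ana$fits), " era strata")
  }

  if ("ncc" %in% stages) {
    co <- load_cohort("ncc")
    cl <- get_claims("ncc")
    s <- load_series("ncc")
    ncc <- run_all_outcomes(cl, co, s, config, seed = seed)
    write_results(ncc$incidence, pth("incidence.csv"))
    for (cd in c("presence", "duration", "cumdose")) {
      write_results(ncc$results[coding == cd],
                    pth(sprintf("results_%s.csv", cd)))
    }
    if (length(ncc$sets)) {
      write_results(
        data.table::rbindlist(ncc$sets, idcol = "outcome")[
          , .(outcome, set_id, patient_id, is_case, event_time, exposed,
              dur_bin, cum_bin)],
        pth("matched_sets.csv"))
    }
    if (nrow(ncc$skipped)) write_results(ncc$skipped, pth("skipped.csv"))
    log_msg("ncc: ", nrow(ncc$incidence), " outcomes assessed")
  }

  files <- sort(list.files(out_dir, recursive = TRUE, full.names = FALSE))
  files <- setdiff(files, "manifest.json")
  digests <- as.list(tools::md5sum(file.path(out_dir, files)))
  names(digests) <- files
  manifest <- list(
    seed = as.integer(seed),
    stages = stages,
    config_hash = unname(tools::md5sum(write_config(
      config, tempfile(fileext = ".yaml")))),
    files = digests,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, pth("manifest.json"), auto_unbox = TRUE)
  invisible(manifest)
}

#' Command-line entry point
#'
#' `itpclaims --stages simulate,cohort,exposure --out DIR [--config FILE]
#' [--seed N] [--n-patients N] [--claims DIR]`. Installed as
#' `exec/itpclaims`; also callable as `itp_cli(c("--stages", ...))`.
#'
#' @param args character vector of command-line arguments.
#' @return exit status 0 invisibly.
#' @export
itp_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  val <- function(flag, default = NULL) {
    i <- which(args == flag)
    if (length(i) && i < length(args)) args[i + 1L] else default
  }
  if ("--help" %in% args || length(args) == 0L) {
    cat("usage: itpclaims --stages s1,s2,... --out DIR",
        "[--config FILE] [--seed N] [--n-patients N] [--claims DIR]\n",
        "stages:", paste(STAGES, collapse = ", "), "\n")
    return(invisible(0L))
  }
  out <- val("--out", "itpclaims_out")
  stages <- strsplit(val("--stages", paste(STAGES, collapse = ",")), ",")[[1]]
  cfg <- val("--config")
  config <- if (is.null(cfg)) itp_config() else read_config(cfg)
  seed <- as.integer(val("--seed", "1"))
  n <- as.integer(val("--n-patients", "2000"))
  run_pipeline(out, stages = stages, config = config,
               sim = sim_params(n_patients = n),
               claims_dir = val("--claims"), seed = seed)
  invisible(0L)
}
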