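# Claims data dictionary, delimited-text readers/writers, and validation.
# One file per entity: patients, diagnoses, prescriptions, procedures.

CLAIMS_SCHEMA <- list(
  patients = c("patient_id", "gender", "birth_year",
               "observation_start", "observation_end"),
  diagnoses = c("patient_id", "date", "code", "suspected", "inpatient"),
  prescriptions = c("patient_id", "date", "drug_class", "drug_name",
                    "route", "daily_dose_mg", "days_supplied"),
  procedures = c("patient_id", "date", "procedure")
)

DRUG_CLASSES <- c("CS", "EPAG", "ROMI", "RTX", "OTHER_IS")

#' Read claims tables from delimited text files
#'
#' Reads the four entity files (patients, diagnoses, prescriptions,
#' procedures), checks the column dictionary, parses dates, and validates the
#' record invariants. Unknown drug classes are remapped to `OTHER_IS` with a
#' warning; rows violating an invariant raise an error naming the row.
#'
#' @param dir directory containing `patients.csv`, `diagnoses.csv`,
#'   `prescriptions.csv`, `procedures.csv`; alternatively pass `paths`.
#' @param paths optional named list/vector of explicit file paths with names
#'   `patients`, `diagnoses`, `prescriptions`, `procedures`.
#' @return a `claims` object: list of four `data.table`s.
#' @export
read_claims <- function(dir = NULL, paths = NULL) {
  if (is.null(paths)) {
    stopifnot(!is.null(dir))
    paths <- file.path(dir, paste0(names(CLAIMS_SCHEMA), ".csv"))
    names(paths) <- names(CLAIMS_SCHEMA)
  }
  tabs <- lapply(names(CLAIMS_SCHEMA), function(ent) {
    path <- paths[[ent]]
    if (!file.exists(path)) stop("missing claims file: ", path, call. = FALSE)
    dt <- data.table::fread(path, colClasses = list(character = "patient_id"),
                            na.strings = "")
    missing_cols <- setdiff(CLAIMS_SCHEMA[[ent]], names(dt))
    if (length(missing_cols)) {
      stop("schema error in ", ent, ": missing column(s) ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    }
    dt <- dt[, CLAIMS_SCHEMA[[ent]], with = FALSE]
    parse_entity(dt, ent)
  })
  names(tabs) <- names(CLAIMS_SCHEMA)
  validate_claims(as_claims(tabs))
}

parse_entity <- function(dt, ent) {
  dt <- data.table::copy(dt)
  if ("date" %in% names(dt)) {
    d <- as.Date(as.character(dt$date), format = "%Y-%m-%d")
    bad <- which(is.na(d) & !is.na(dt$date))
    if (length(bad)) {
      stop("unparseable date in ", ent, " at row(s) ",
           paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
    }
    dt[, date := d]
  }
  if (ent == "patients") {
    dt[, `:=`(gender = as.character(gender),
              birth_year = as.integer(birth_year),
              observation_start = as.character(observation_start),
              observation_end = as.character(observation_end))]
  }
  if (ent == "diagnoses") {
    dt[, `:=`(code = as.character(code),
              suspected = as.logical(suspected),
              inpatient = as.logical(inpatient))]
  }
  if (ent == "prescriptions") {
    dt[, `:=`(drug_class = as.character(drug_class),
              drug_name = as.character(drug_name),
              route = as.character(route),
              daily_dose_mg = as.numeric(daily_dose_mg),
              days_supplied = as.integer(days_supplied))]
    unknown <- !dt$drug_class %in% DRUG_CLASSES
    if (any(unknown)) {
      warning(sum(unknown), " prescription(s) with unknown drug class mapped ",
              "to OTHER_IS: ",
              paste(unique(dt$drug_class[unknown]), collapse = ", "),
              call. = FALSE)
      dt[unknown, drug_class := "OTHER_IS"]
    }
  }
  dt
}

as_claims <- function(tabs) structure(tabs, class = "claims")

#' @export
print.claims <- function(x, ...) {
  cat("<claims>", nrow(x$patients), "patients;",
      nrow(x$diagnoses), "diagnoses;",
      nrow(x$prescriptions), "prescriptions;",
      nrow(x$procedures), "procedures\n")
  invisible(x)
}

#' Validate claims tables against the record invariants
#'
#' Checks gender levels, enrollment ordering, non-negative doses, positive
#' days supplied, and route values. Raises an error listing offending rows;
#' rows are never silently dropped.
#' @param claims a `claims` object.
#' @return the validated `claims` object, invisibly usable downstream.
#' @export
validate_claims <- function(claims) {
  p <- claims$patients
  err <- function(ent, rows, what) {
    stop("validation error in ", ent, ": ", what, " at row(s) ",
         paste(utils::head(rows, 5L), collapse = ", "),
         if (length(rows) > 5L) sprintf(" (and %d more)", length(rows) - 5L),
         call. = FALSE)
  }
  bad <- which(!p$gender %in% c("female", "male"))
  if (length(bad)) err("patients", bad, "gender not in {female, male}")
  bad <- which(month_start(p$observation_start) > month_start(p$observation_end))
  if (length(bad)) err("patients", bad, "observation_start > observation_end")
  rx <- claims$prescriptions
  bad <- which(rx$daily_dose_mg < 0)
  if (length(bad)) err("prescriptions", bad, "daily_dose_mg < 0")
  bad <- which(is.na(rx$days_supplied) | rx$days_supplied < 1L)
  if (length(bad)) err("prescriptions", bad, "days_supplied < 1")
  bad <- which(!rx$route %in% c("oral", "injection"))
  if (length(bad)) err("prescriptions", bad, "route not in {oral, injection}")
  claims
}

#' Write a result table as deterministic delimited text
#'
#' Columns are written in their current order; `NA` cells become empty
#' strings and are restored as missing by [read_results()]. Dates are
#' ISO-formatted so the file round-trips.
#' @param table a data.frame/data.table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(table, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  data.table::fwrite(data.table::as.data.table(table), path, na = "",
                     dateTimeAs = "ISO")
  invisible(path)
}

#' Read back a table written by [write_results()]
#' @param path file path.
#' @return a `data.table`.
#' @export
read_results <- function(path) {
  data.table::fread(path, na.strings = "")
}

#' Write claims tables to a directory as the four entity CSVs
#' @param claims a `claims` object.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_claims <- function(claims, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (ent in names(CLAIMS_SCHEMA)) {
    write_results(claims[[ent]], file.path(dir, paste0(ent, ".csv")))
  }
  invisible(dir)
}
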