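# Calendar helpers. Prescription/diagnosis dates are day-level Date objects;
# enrollment is month-level and stored as "YYYY-MM" strings in the files.

#' First day of the month containing a date or "YYYY-MM" string
#' @param x Date vector or "YYYY-MM" character vector
#' @return Date vector (day = 1)
#' @keywords internal
month_start <- function(x) {
  if (is.character(x)) {
    return(as.Date(paste0(x, "-01")))
  }
  as.Date(format(x, "%Y-%m-01"))
}

#' Last day of the month containing a date or "YYYY-MM" string
#' @param x Date vector or "YYYY-MM" character vector
#' @return Date vector
#' @keywords internal
month_end <- function(x) {
  add_months(month_start(x), 1L) - 1L
}

#' Shift a month-start Date by whole calendar months
#' @param x Date vector, assumed day-of-month 1
#' @param k integer number of months (may be negative)
#' @return Date vector
#' @keywords internal
add_months <- function(x, k) {
  lt <- as.POSIXlt(x)
  lt$mon <- lt$mon + k
  as.Date(lt)
}

#' Format a Date as "YYYY-MM"
#' @param x Date vector
#' @keywords internal
ym <- function(x) format(x, "%Y-%m")

#' Calendar year of a Date as integer
#' @param x Date vector
#' @keywords internal
year_of <- function(x) as.integer(format(x, "%Y"))
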