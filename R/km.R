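# Kaplan-Meier product-limit estimation, log-rank test, and the per-era
# time-to-withdrawal analysis.

#' Kaplan-Meier product-limit fit
#'
#' Standard product-limit estimator with Greenwood variance. The pointwise
#' 95% CI uses the log(-log) transform by default (plain Greenwood on the
#' survival scale optionally). The median is the smallest time with
#' `S(t) <= 0.5`; its CI endpoints are the smallest times at which the upper /
#' lower confidence curves drop to 0.5 or below (NA when never reached).
#'
#' @param times non-negative event/censoring times.
#' @param events logical (TRUE = event, FALSE = censored).
#' @param conf_method "loglog" (default) or "plain".
#' @param group optional group label carried through.
#' @return object of class `km_fit`: data.table `curve` (`time`, `n_risk`,
#'   `n_event`, `n_censor`, `surv`, `se`, `lower`, `upper`), `median`,
#'   `median_ci`, `n`, `group`.
#' @export
km_fit <- function(times, events, conf_method = "loglog", group = NA) {
  stopifnot(length(times) == length(events))
  if (length(times) == 0L) stop("empty input", call. = FALSE)
  if (any(times < 0)) stop("negative times", call. = FALSE)
  events <- as.logical(events)
  ut <- sort(unique(times))
  n_risk <- vapply(ut, function(t) sum(times >= t), numeric(1))
  n_event <- vapply(ut, function(t) sum(times == t & events), numeric(1))
  n_censor <- vapply(ut, function(t) sum(times == t & !events), numeric(1))
  surv <- cumprod(1 - n_event / n_risk)
  # Greenwood: var(S) = S^2 * sum d / (n (n - d))
  gw <- cumsum(ifelse(n_risk > n_event, n_event / (n_risk * (n_risk - n_event)),
                      0))
  se <- surv * sqrt(gw)
  z <- stats::qnorm(0.975)
  if (conf_method == "loglog") {
    ok <- surv > 0 & surv < 1
    se_ll <- sqrt(gw) / abs(log(surv))
    lower <- upper <- surv
    lower[ok] <- surv[ok]^exp(z * se_ll[ok])
    upper[ok] <- surv[ok]^exp(-z * se_ll[ok])
    lower[surv == 0] <- 0
    upper[surv == 0] <- 0
    lower[surv == 1] <- 1
    upper[surv == 1] <- 1
  } else {
    lower <- pmax(surv - z * se, 0)
    upper <- pmin(surv + z * se, 1)
  }
  curve <- data.table::data.table(time = ut, n_risk = n_risk,
                                  n_event = n_event, n_censor = n_censor,
                                  surv = surv, se = se,
                                  lower = lower, upper = upper)
  med_from <- function(s) {
    i <- which(s <= 0.5 + 1e-12)
    if (length(i)) ut[i[1L]] else NA_real_
  }
  structure(list(curve = curve,
                 median = med_from(surv),
                 median_ci = c(lower = med_from(lower),
                               upper = med_from(upper)),
                 n = length(times), n_events = sum(events), group = group),
            class = "km_fit")
}

#' @export
print.km_fit <- function(x, ...) {
  cat(sprintf("<km_fit> n=%d events=%d median=%s (95%% CI %s-%s)\n",
              x$n, x$n_events, format(x$median),
              format(x$median_ci[["lower"]]), format(x$median_ci[["upper"]])))
  invisible(x)
}

#' Survival probability of a fitted curve at given times
#' @param fit a `km_fit` object.
#' @param at numeric times.
#' @return numeric vector of `S(at)` (1 before the first event time).
#' @export
km_surv_at <- function(fit, at) {
  idx <- findInterval(at, fit$curve$time)
  ifelse(idx == 0L, 1, fit$curve$surv[pmax(idx, 1L)])
}

#' Two-sample log-rank test
#'
#' One-degree-of-freedom log-rank statistic from the usual observed-minus-
#' expected sums over the pooled event times, with a chi-square tail p-value.
#' Identical groups give statistic 0 and p = 1.
#'
#' @param times_a,events_a times and event indicators of group A.
#' @param times_b,events_b times and event indicators of group B.
#' @return list: `chi_square`, `p`, `observed`, `expected` (per group).
#' @export
logrank <- function(times_a, events_a, times_b, events_b) {
  if (!length(times_a) || !length(times_b)) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  times <- c(times_a, times_b)
  events <- as.logical(c(events_a, events_b))
  grp <- rep(c(0L, 1L), c(length(times_a), length(times_b)))
  ut <- sort(unique(times[events]))
  o_a <- e_a <- v <- 0
  for (t in ut) {
    at_risk <- times >= t
    n <- sum(at_risk)
    n_a <- sum(at_risk & grp == 0L)
    d <- sum(events & times == t)
    d_a <- sum(events & times == t & grp == 0L)
    o_a <- o_a + d_a
    e_a <- e_a + d * n_a / n
    if (n > 1) {
      v <- v + d * (n_a / n) * (1 - n_a / n) * (n - d) / (n - 1)
    }
  }
  chi <- if (v > 0) (o_a - e_a)^2 / v else 0
  list(chi_square = chi, p = stats::pchisq(chi, df = 1L, lower.tail = FALSE),
       observed = c(a = o_a, b = sum(events) - o_a),
       expected = c(a = e_a, b = sum(events) - e_a))
}

#' Per-era time-to-withdrawal analysis
#'
#' For each calendar era with at least one CS initiator: the all-initiator
#' Kaplan-Meier fit (median with 95% CI, survival at 1 and 3 months) plus the
#' descriptive median/IQR of event times among patients who actually withdrew
#' (the event-only summary), and a log-rank test across eras when two or more
#' are present. The two medians answer different questions and are labelled
#' distinctly.
#'
#' @param withdrawal output of [withdrawal_time()].
#' @param config an [itp_config()] object.
#' @return list: `fits` (named list of `km_fit`), `event_only` (data.table of
#'   descriptive medians/IQR), `surv_at` (survival at 30/90 days per era),
#'   `logrank` (NULL for a single era).
#' @export
withdrawal_analysis <- function(withdrawal, config = itp_config()) {
  wd <- withdrawal[!is.na(era)]
  eras <- names(config$era_years)
  fits <- list()
  ev_rows <- list()
  sa_rows <- list()
  for (e in eras) {
    sub <- wd[era == e]
    if (nrow(sub) == 0L) {
      warning("no CS initiators in era ", e, "; stratum omitted",
              call. = FALSE)
      next
    }
    fit <- km_fit(sub$time, sub$event,
                  conf_method = config$median_ci_method, group = e)
    fits[[e]] <- fit
    evt <- sub[event == TRUE, time]
    ev_rows[[e]] <- data.table::data.table(
      era = e, n = nrow(sub), n_events = length(evt),
      median = if (length(evt)) stats::median(evt) else NA_real_,
      q1 = if (length(evt)) unname(stats::quantile(evt, 0.25, type = 2))
           else NA_real_,
      q3 = if (length(evt)) unname(stats::quantile(evt, 0.75, type = 2))
           else NA_real_)
    sa_rows[[e]] <- data.table::data.table(
      era = e, surv_1m = km_surv_at(fit, 30), surv_3m = km_surv_at(fit, 90))
  }
  lr <- NULL
  if (length(fits) >= 2L) {
    a <- wd[era == names(fits)[1L]]
    b <- wd[era == names(fits)[2L]]
    lr <- logrank(a$time, a$event, b$time, b$event)
  }
  list(fits = fits,
       event_only = data.table::rbindlist(ev_rows),
       surv_at = data.table::rbindlist(sa_rows),
       logrank = lr)
}
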