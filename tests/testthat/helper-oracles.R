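# Independent brute-force oracles used across the suite. These deliberately
# share no code with the package implementations they check.

if (requireNamespace("survival", quietly = TRUE)) {
  suppressMessages(library(survival))
}

# day-by-day boolean-array episode oracle (oral rule): covered days are the
# union of prescription day sets; coverage runs are merged when the gap from
# a run's end (exclusive) to the next run's start is <= gap_days
oracle_episodes_oral <- function(dates, days_supplied, gap_days) {
  stopifnot(length(dates) == length(days_supplied))
  d0 <- min(dates)
  horizon <- max(dates + days_supplied) - d0 + 1L
  covered <- rep(FALSE, horizon)
  for (i in seq_along(dates)) {
    idx <- (dates[i] - d0 + 1L):(dates[i] + days_supplied[i] - d0)
    covered[idx] <- TRUE
  }
  r <- rle(covered)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(start = starts[r$values], end = ends[r$values])
  if (nrow(runs) == 0L) return(runs)
  ep <- 1L
  eps <- integer(nrow(runs))
  eps[1L] <- 1L
  for (i in seq_len(nrow(runs) - 1L)) {
    gap <- runs$start[i + 1L] - (runs$end[i] + 1L)
    if (gap > gap_days) ep <- ep + 1L
    eps[i + 1L] <- ep
  }
  out <- do.call(rbind, lapply(split(runs, eps), function(g) {
    data.frame(start = min(g$start), end = max(g$end))
  }))
  data.frame(start = d0 + out$start - 1L, end = d0 + out$end - 1L)
}

# textbook O-E/V log-rank accumulation over a hypergeometric 2xK table
oracle_logrank <- function(t1, e1, t2, e2) {
  tt <- c(t1, t2); ee <- c(e1, e2)
  g <- rep(1:2, c(length(t1), length(t2)))
  o <- e <- v <- 0
  for (u in sort(unique(tt[ee == 1]))) {
    n <- sum(tt >= u); n1 <- sum(tt >= u & g == 1)
    d <- sum(tt == u & ee == 1); d1 <- sum(tt == u & ee == 1 & g == 1)
    o <- o + d1
    e <- e + d * n1 / n
    if (n > 1) v <- v + d * n1 * (n - n1) * (n - d) / (n^2 * (n - 1))
  }
  chi <- (o - e)^2 / v
  list(chi_square = chi, p = pchisq(chi, 1, lower.tail = FALSE))
}

# hand product-limit estimator
oracle_km <- function(times, events) {
  ut <- sort(unique(times))
  s <- 1
  out <- numeric(length(ut))
  for (i in seq_along(ut)) {
    n <- sum(times >= ut[i])
    d <- sum(times == ut[i] & events)
    s <- s * (1 - d / n)
    out[i] <- s
  }
  data.frame(time = ut, surv = out)
}

# brute-force per-day active-set scan, run-length encoded
oracle_states <- function(intervals) {
  # intervals: data.frame(label, start, end) in integer days
  if (nrow(intervals) == 0L) return(data.frame())
  days <- min(intervals$start):max(intervals$end)
  lab <- vapply(days, function(d) {
    act <- sort(unique(intervals$label[intervals$start <= d &
                                         intervals$end >= d]))
    paste(act, collapse = "|")
  }, "")
  keep <- lab != ""
  r <- rle(lab)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  st <- data.frame(start = days[starts], end = days[ends], label = r$values)
  st <- st[st$label != "", , drop = FALSE]
  # merge consecutive identical labels across gaps
  if (nrow(st) > 1L) {
    grp <- cumsum(c(TRUE, st$label[-1L] != st$label[-nrow(st)]))
    st <- do.call(rbind, lapply(split(st, grp), function(g) {
      data.frame(start = min(g$start), end = max(g$end), label = g$label[1L])
    }))
  }
  rownames(st) <- NULL
  st
}

# random prescription table for one patient and class
random_rx <- function(n, patient = "X", class = "CS", route = "oral") {
  data.table::data.table(
    patient_id = patient,
    date = as.Date("2018-01-01") + sort(sample.int(400L, n, replace = TRUE)),
    drug_class = class, drug_name = "prednisolone", route = route,
    daily_dose_mg = 10, days_supplied = sample.int(40L, n, replace = TRUE))
}
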