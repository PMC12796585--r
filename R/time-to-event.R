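# Time from cohort index to first subsequent target event, with
# administrative right-censoring, a product-limit survival estimate, and
# the summaries an operational question needs (median, cumulative incidence
# at days of interest).

#' Time to first target event after cohort entry
#'
#' For each cohort member, the number of days from their index date to the
#' first event matching `target` on or after the index (same-day events count
#' as time 0 — date-resolution data cannot order within a day). Members with
#' no such event are censored at `min(horizon, coverage end - index)`.
#'
#' @param dataset an `ehr_dataset`.
#' @param cohort a `cohort`.
#' @param target an include-style [criterion()] describing the event.
#' @param horizon administrative follow-up limit in days (`> 0`, default 28).
#' @return tibble of class `duration_records`: `patient_id`, `time` (days),
#'   `event` (`TRUE` = observed, `FALSE` = censored).
#' @export
time_to_first_event <- function(dataset, cohort, target, horizon = 28) {
  stopifnot(inherits(target, "criterion"))
  if (target$mode != "include") abort("`target` must be an include-style criterion")
  if (horizon <= 0) abort("`horizon` must be positive")
  ev <- criterion_events(dataset, target)
  end <- dataset$coverage_window[2]
  rows <- lapply(seq_len(nrow(cohort)), function(k) {
    idx <- cohort$index_date[k]
    cens <- min(horizon, as.numeric(end - idx))
    d <- ev$event_date[ev$patient_id == cohort$patient_id[k] & ev$event_date >= idx]
    t_first <- if (length(d)) as.numeric(min(d) - idx) else Inf
    if (t_first <= cens) {
      tibble(patient_id = cohort$patient_id[k], time = t_first, event = TRUE)
    } else {
      tibble(patient_id = cohort$patient_id[k], time = cens, event = FALSE)
    }
  })
  structure(bind_rows(rows), class = c("duration_records", "tbl_df", "tbl", "data.frame"))
}

#' Kaplan-Meier product-limit estimate
#'
#' `S(t) = prod_{t_i <= t} (1 - d_i / n_i)` over distinct observed event
#' times, with the standard tie convention that events precede censorings at
#' equal times (a record censored at `t` is still at risk for an event at
#' `t`).
#'
#' @param records a `duration_records` tibble (or any data frame with
#'   numeric `time >= 0` and logical `event`).
#' @return object of class `survival_curve`: tibble with `time`, `n_risk`,
#'   `n_event`, `n_censor`, `surv`, plus attribute `n0` (records at entry).
#'   Rows exist only at event times; `S` starts at 1 and is non-increasing.
#' @export
kaplan_meier <- function(records) {
  if (nrow(records) == 0L) abort("`records` must be non-empty")
  if (any(records$time < 0)) abort("durations must be non-negative")
  tt <- records$time
  ee <- records$event
  times <- sort(unique(tt[ee]))
  n0 <- length(tt)
  s <- 1
  rows <- lapply(times, function(t) {
    n_risk <- sum(tt >= t)               # censored at t still at risk
    d <- sum(tt == t & ee)
    c_ <- sum(tt == t & !ee)
    s <<- s * (1 - d / n_risk)
    tibble(time = t, n_risk = n_risk, n_event = d, n_censor = c_, surv = s)
  })
  out <- if (length(rows)) bind_rows(rows) else
    tibble(time = numeric(), n_risk = numeric(), n_event = numeric(),
           n_censor = numeric(), surv = numeric())
  structure(out, n0 = n0, class = c("survival_curve", class(out)))
}

#' Evaluate a survival curve at given times
#' @param curve a `survival_curve`.
#' @param t numeric vector of days.
#' @return `S(t)` as a numeric vector (1 before the first event time).
#' @export
surv_at <- function(curve, t) {
  vapply(t, function(d) {
    i <- which(curve$time <= d)
    if (length(i)) curve$surv[max(i)] else 1
  }, numeric(1))
}

#' Summarise a survival curve
#'
#' Median time-to-event (the first time with `S(t) <= 0.5`; flagged not
#' reached if the curve never crosses 0.5) and cumulative incidence
#' `1 - S(d)` at each requested day.
#'
#' @param curve a `survival_curve`.
#' @param days_of_interest numeric vector of days (default `c(3, 7, 14, 28)`).
#' @return object of class `tte_summary`: list with `median`,
#'   `median_reached`, and `incidence` (tibble `day`, `cum_incidence`).
#' @export
tte_summary <- function(curve, days_of_interest = c(3, 7, 14, 28)) {
  crossed <- which(curve$surv <= 0.5)
  med <- if (length(crossed)) curve$time[min(crossed)] else NA_real_
  structure(
    list(median = med, median_reached = length(crossed) > 0,
         incidence = tibble(day = days_of_interest,
                            cum_incidence = 1 - surv_at(curve, days_of_interest))),
    class = "tte_summary"
  )
}

#' @export
print.tte_summary <- function(x, ...) {
  if (x$median_reached) {
    cat(sprintf("median time to event: %g day(s)\n", x$median))
  } else {
    cat("median time to event: not reached\n")
  }
  print(x$incidence)
  invisible(x)
}
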