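# Descriptive analytics: demographics overview tables and patient-level
# event-frequency analysis, both with small-cell suppression.

age_years <- function(from, to) as.numeric(to - from) / 365.25

#' Demographics overview table
#'
#' Per cohort: member count, sex split (count and percentage), age at cohort
#' entry (median and quartiles, decimal years = days/365.25), and median
#' follow-up from index to the coverage end. All counts below `threshold`
#' are suppressed. A cohort with zero members yields empty/suppressed cells,
#' not an error.
#'
#' @param dataset an `ehr_dataset`.
#' @param cohorts a `cohort` or list of cohorts.
#' @param threshold small-cell suppression threshold (default 5).
#' @return a [result_table()] with columns `cohort`, `statistic`, `count`,
#'   `pct`, `value`.
#' @export
demographics_overview <- function(dataset, cohorts, threshold = 5) {
  if (inherits(cohorts, "cohort")) cohorts <- list(cohorts)
  if (!length(cohorts)) abort("`cohorts` must contain at least one cohort")
  rows <- lapply(cohorts, function(co) {
    nm <- cohort_name(co)
    n <- nrow(co)
    base <- tibble(cohort = nm, statistic = "n", count = n, pct = NA_real_,
                   value = NA_real_)
    if (n == 0L) {
      return(bind_rows(base, tibble(
        cohort = nm,
        statistic = c("sex_female", "sex_male", "sex_other",
                      "age_entry_median_years", "age_entry_q25_years",
                      "age_entry_q75_years", "followup_median_days"),
        count = NA_real_, pct = NA_real_, value = NA_real_
      )))
    }
    mem <- left_join(as_tibble(co), dataset$patients, by = "patient_id")
    sex_n <- unname(vapply(SEX_LEVELS, function(s) sum(mem$sex == s, na.rm = TRUE),
                           numeric(1)))
    ages <- age_years(mem$date_of_birth, mem$index_date)
    fup <- as.numeric(dataset$coverage_window[2] - mem$index_date)
    bind_rows(
      base,
      tibble(cohort = nm, statistic = paste0("sex_", SEX_LEVELS),
             count = sex_n, pct = 100 * sex_n / n, value = NA_real_),
      tibble(cohort = nm,
             statistic = c("age_entry_median_years", "age_entry_q25_years",
                           "age_entry_q75_years", "followup_median_days"),
             count = NA_real_, pct = NA_real_,
             value = c(median(ages), quantile(ages, 0.25, names = FALSE),
                       quantile(ages, 0.75, names = FALSE), median(fup)))
    )
  })
  tab <- result_table(bind_rows(rows), count_cols = "count",
                      pct_map = c(count = "pct"))
  suppress_small_counts(tab, threshold)
}

#' Patient-level event-frequency analysis
#'
#' For each group value (code, display label, generic name or therapeutic
#' class) reports the percentage of cohort members with at least one matching
#' event in the window — patient-level counting, so repeating an event never
#' changes a frequency. Sorted by frequency (descending), ties broken
#' alphabetically by label, truncated to `top_k`; underlying counts are
#' suppressed below `threshold`.
#'
#' @param dataset an `ehr_dataset`.
#' @param cohort a non-empty `cohort`.
#' @param domain event domain to analyse.
#' @param group_by `"code"`, `"display"`, `"generic_name"` or
#'   `"therapeutic_class"` (the last two restrict medication events to that
#'   vocabulary and group by its display label).
#' @param window `"after_index"` (event on/after the member's index date, up
#'   to the coverage end) or `"ever"`.
#' @param top_k number of rows to keep (default all).
#' @param threshold small-cell suppression threshold (default 5).
#' @return a [result_table()] with columns `label`, `count`, `pct`.
#' @export
frequency_analysis <- function(dataset, cohort, domain,
                               group_by = c("code", "display", "generic_name",
                                            "therapeutic_class"),
                               window = c("after_index", "ever"),
                               top_k = Inf, threshold = 5) {
  group_by <- arg_match(group_by)
  window <- arg_match(window)
  if (!domain %in% EVENT_DOMAINS) abort(paste("unknown domain:", domain))
  if (nrow(cohort) == 0L) abort("`cohort` has no members")

  ev <- dataset$events[[domain]]
  if (group_by %in% c("generic_name", "therapeutic_class")) {
    ev <- ev[ev$code_system == group_by, ]
    ev$label <- ev$display
  } else {
    ev$label <- ev[[if (group_by == "code") "code" else "display"]]
  }
  ev <- semi_join(ev, as_tibble(cohort), by = "patient_id")
  if (window == "after_index") {
    ev <- left_join(ev, as_tibble(cohort)[, c("patient_id", "index_date")],
                    by = "patient_id")
    ev <- ev[ev$event_date >= ev$index_date, ]
  }
  n <- nrow(cohort)
  freq <- ev %>%
    distinct(patient_id, label) %>%
    count(label, name = "count") %>%
    mutate(pct = 100 * count / n) %>%
    arrange(dplyr::desc(pct), label)
  if (is.finite(top_k)) freq <- head(freq, top_k)
  tab <- result_table(freq, count_cols = "count", pct_map = c(count = "pct"))
  suppress_small_counts(tab, threshold)
}
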