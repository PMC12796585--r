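# Figure builders. Each returns a ggplot object; save with ggplot2::ggsave
# (SVG or PNG) as needed.

#' Bar chart of an event-frequency table
#' @param table a [frequency_analysis()] result.
#' @return a ggplot object (suppressed rows are omitted).
#' @export
plot_frequency <- function(table) {
  df <- as_tibble(table)
  df <- df[!is.na(df$pct), ]
  df$label <- factor(df$label, levels = rev(df$label))
  ggplot2::ggplot(df, ggplot2::aes(x = pct, y = label)) +
    ggplot2::geom_col(fill = "#33658a") +
    ggplot2::labs(x = "% of cohort members with ≥ 1 event", y = NULL) +
    ggplot2::xlim(0, 100) +
    ggplot2::theme_minimal()
}

#' Density curves of age at cohort entry
#' @param comparison an [age_at_entry_comparison()] result.
#' @return a ggplot object.
#' @export
plot_age_comparison <- function(comparison) {
  ggplot2::ggplot(comparison$density,
                  ggplot2::aes(x = age, y = density, colour = cohort)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "age at cohort entry (years)", y = "density") +
    ggplot2::theme_minimal()
}

#' Step plot of a survival curve
#' @param curve a [kaplan_meier()] result.
#' @param incidence plot cumulative incidence `1 - S(t)` instead of `S(t)`.
#' @return a ggplot object.
#' @export
plot_survival_curve <- function(curve, incidence = FALSE) {
  df <- bind_rows(tibble(time = 0, surv = 1), as_tibble(curve)[, c("time", "surv")])
  if (incidence) df$surv <- 1 - df$surv
  ggplot2::ggplot(df, ggplot2::aes(x = time, y = surv)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "days since index",
                  y = if (incidence) "cumulative incidence" else "S(t)") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Forest plot of a relative-risk scan
#' @param scan a [relative_risk_scan()] result.
#' @return a ggplot object (log-scaled axis).
#' @export
plot_rr_scan <- function(scan) {
  df <- as_tibble(scan)
  df$code <- factor(df$code, levels = rev(df$code))
  ggplot2::ggplot(df, ggplot2::aes(x = rr, y = code)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = ci_low, xmax = ci_high),
                            height = 0.2) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "relative risk (log scale)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Consult overlay: raw values, centile curves and patient z-scores
#' @param report a [consult()] result.
#' @return a ggplot object with the comparator centile fan, comparator raw
#'   observations, and the patient's observations highlighted.
#' @export
plot_consult <- function(report) {
  curves <- report$centile_curves
  curves$centile <- factor(curves$centile)
  ggplot2::ggplot() +
    ggplot2::geom_point(data = report$comparator_obs,
                        ggplot2::aes(x = time, y = value),
                        colour = "grey70", alpha = 0.5, size = 0.8) +
    ggplot2::geom_line(data = curves,
                       ggplot2::aes(x = time, y = value, group = centile,
                                    linetype = centile),
                       colour = "#33658a") +
    ggplot2::geom_point(data = report$scores,
                        ggplot2::aes(x = time, y = value),
                        colour = "#d1495b", size = 2) +
    ggplot2::labs(x = "days since index", y = report$observation_code) +
    ggplot2::theme_minimal()
}
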