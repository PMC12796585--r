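# The informatics consult: place one patient's longitudinal observations
# against a reference model fitted to a comparator cohort of similar
# previous patients.

cohort_observations <- function(dataset, cohort, observation_code, window) {
  obs <- dataset$events$observation
  obs <- obs[obs$code == normalize_code(observation_code), ]
  obs <- left_join(obs, as_tibble(cohort)[, c("patient_id", "index_date")],
                   by = "patient_id")
  obs <- obs[!is.na(obs$index_date), ]
  obs$time <- as.numeric(obs$event_date - obs$index_date)
  obs[obs$time >= window[1] & obs$time <= window[2],
      c("patient_id", "time", "value")]
}

#' Informatics consult: score one patient against a comparator cohort
#'
#' Fits a reference model to the comparator cohort's observations of
#' `observation_code` within `window` days of each member's index date
#' (SHASH family by default), fits the patient's own trajectory with a
#' Logistic model where enough observations exist, and reports a
#' per-observation z-score/centile table plus the data for a raw-values
#' overlay and centile-curve display.
#'
#' @param dataset an `ehr_dataset`.
#' @param patient a `cohort` with exactly one member (the patient of
#'   interest).
#' @param comparator the reference `cohort`.
#' @param observation_code observation concept code (e.g. a serum-creatinine
#'   code).
#' @param window analysis window in days since index (default `c(7, 730)`,
#'   one week to two years post-entry).
#' @param comparator_family,patient_family distribution families (defaults:
#'   SHASH for the cohort, Logistic for the single patient).
#' @param smooth a [smooth_spec()] for the comparator model. The patient
#'   model reuses it with the basis dimension capped at a third of the
#'   patient's observation count (minimum 4); with fewer than 8 observations
#'   no patient curve is fitted.
#' @param centiles centile curves to tabulate.
#' @return object of class `consult_report`: list with `patient_id`,
#'   `observation_code`, `window`, `comparator_model`, `patient_model`
#'   (possibly `NULL`), `scores` (z/centile per patient observation),
#'   `comparator_obs` (overlay points), `centile_curves`, and `n` counts.
#' @export
consult <- function(dataset, patient, comparator, observation_code,
                    window = c(7, 730),
                    comparator_family = "shash", patient_family = "logistic",
                    smooth = smooth_spec(), centiles = c(0.05, 0.25, 0.5, 0.75, 0.95)) {
  if (nrow(patient) != 1L) {
    abort(sprintf("`patient` must be a cohort of exactly one member (got %d)", nrow(patient)))
  }
  pat_obs <- cohort_observations(dataset, patient, observation_code, window)
  if (nrow(pat_obs) == 0L) {
    abort(sprintf("patient %s has no \"%s\" observations within %g-%g days of index",
                  patient$patient_id[1], observation_code, window[1], window[2]))
  }
  cmp_obs <- cohort_observations(dataset, comparator, observation_code, window)
  if (nrow(cmp_obs) == 0L) {
    abort("comparator cohort has no in-window observations to model")
  }

  cmp_model <- fit_reference_model(cmp_obs$time, cmp_obs$value,
                                   family = comparator_family, smooth = smooth)
  pat_model <- NULL
  if (nrow(pat_obs) >= 8L) {
    pat_smooth <- smooth
    pat_smooth$n_basis <- max(4L, min(smooth$n_basis, floor(nrow(pat_obs) / 3)))
    pat_model <- fit_reference_model(pat_obs$time, pat_obs$value,
                                     family = patient_family, smooth = pat_smooth)
  }

  scores <- zscore(cmp_model, pat_obs$time, pat_obs$value)
  grid <- seq(cmp_model$t_range[1], cmp_model$t_range[2], length.out = 101)
  structure(
    list(patient_id = patient$patient_id[1],
         observation_code = normalize_code(observation_code),
         window = window,
         comparator_model = cmp_model, patient_model = pat_model,
         scores = scores, comparator_obs = cmp_obs,
         centile_curves = predict_centiles(cmp_model, grid, centiles),
         n = list(patient_obs = nrow(pat_obs),
                  comparator_obs = nrow(cmp_obs),
                  comparator_members = nrow(comparator))),
    class = "consult_report"
  )
}

#' @export
print.consult_report <- function(x, ...) {
  cat(sprintf("<consult_report> patient %s vs %d comparator member(s), code %s\n",
              x$patient_id, x$n$comparator_members, x$observation_code))
  cat(sprintf("  %d patient observation(s) in window [%g, %g] days; median centile %.3f\n",
              x$n$patient_obs, x$window[1], x$window[2], median(x$scores$centile)))
  invisible(x)
}

#' Serialize a consult report to JSON
#' @param report a `consult_report`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_consult_report <- function(report, path) {
  out <- list(
    patient_id = report$patient_id,
    observation_code = report$observation_code,
    window = report$window, n = report$n,
    scores = as.list(report$scores),
    centile_curves = as.list(report$centile_curves),
    comparator_model = list(family = report$comparator_model$family,
                            nu = report$comparator_model$nu,
                            tau = report$comparator_model$tau,
                            t_range = report$comparator_model$t_range,
                            diagnostics = report$comparator_model$diagnostics)
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
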