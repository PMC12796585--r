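# Common data model: one patients table plus one event table per domain.
# Events are the atoms — a coded (and, for observations, valued) fact about a
# patient on a calendar date. Everything downstream (cohorts, analytics,
# reference models) consumes only this layout.

EVENT_DOMAINS <- c("diagnosis", "procedure", "medication", "observation")
DOMAIN_TABLES <- c(
  diagnosis = "diagnoses", procedure = "procedures",
  medication = "medications", observation = "observations"
)
SEX_LEVELS <- c("female", "male", "other")

empty_events <- function(domain) {
  ev <- tibble(
    patient_id = character(), code_system = character(), code = character(),
    display = character(), event_date = as.Date(character())
  )
  if (domain == "observation") {
    ev$value <- numeric()
    ev$unit <- character()
  }
  ev
}

sort_events <- function(ev) ev[order(ev$patient_id, ev$event_date, ev$code), , drop = FALSE]

#' Construct an EHR dataset
#'
#' Bundles a patients table with per-domain event tables and a dataset
#' coverage window (the administrative start and end dates of data capture,
#' used as the censoring horizon in time-to-event analyses).
#'
#' @param patients tibble with columns `patient_id`, `date_of_birth` (Date),
#'   `sex` (one of `"female"`, `"male"`, `"other"`).
#' @param events named list of event tibbles, one per domain
#'   (`diagnosis`, `procedure`, `medication`, `observation`); each has columns
#'   `patient_id`, `code_system`, `code`, `display`, `event_date`, and
#'   observations additionally `value`, `unit`. Missing domains become empty
#'   tables. Codes are normalized on construction.
#' @param coverage_window length-2 Date vector, start and end of data capture.
#' @return an object of class `ehr_dataset`.
#' @seealso [read_dataset()], [write_dataset()], [validate_dataset()]
#' @export
ehr_dataset <- function(patients, events = list(), coverage_window) {
  coverage_window <- as.Date(coverage_window)
  stopifnot(length(coverage_window) == 2L, !anyNA(coverage_window),
            coverage_window[1] <= coverage_window[2])
  patients <- as_tibble(patients)
  req <- c("patient_id", "date_of_birth", "sex")
  if (!all(req %in% names(patients))) {
    abort(paste0("patients table is missing column(s): ",
                 paste(setdiff(req, names(patients)), collapse = ", ")))
  }
  patients$patient_id <- as.character(patients$patient_id)
  patients$date_of_birth <- as.Date(patients$date_of_birth)
  patients$sex <- as.character(patients$sex)
  patients <- patients[order(patients$patient_id), req]

  evs <- lapply(EVENT_DOMAINS, function(d) {
    ev <- events[[d]]
    if (is.null(ev) || nrow(ev) == 0L) return(empty_events(d))
    ev <- as_tibble(ev)
    ev$patient_id <- as.character(ev$patient_id)
    ev$code_system <- as.character(ev$code_system)
    ev$code <- normalize_code(as.character(ev$code))
    ev$display <- as.character(ev$display)
    ev$event_date <- as.Date(ev$event_date)
    if (d == "observation") {
      if (is.null(ev$value)) ev$value <- NA_real_
      if (is.null(ev$unit)) ev$unit <- NA_character_
      ev$value <- as.numeric(ev$value)
      ev$unit <- as.character(ev$unit)
      ev <- ev[, c("patient_id", "code_system", "code", "display",
                   "event_date", "value", "unit")]
    } else {
      ev <- ev[, c("patient_id", "code_system", "code", "display", "event_date")]
    }
    sort_events(ev)
  })
  names(evs) <- EVENT_DOMAINS

  structure(
    list(patients = patients, events = evs, coverage_window = coverage_window),
    class = "ehr_dataset"
  )
}

#' @export
print.ehr_dataset <- function(x, ...) {
  cat("<ehr_dataset>\n")
  cat("  patients:", nrow(x$patients), "\n")
  for (d in EVENT_DOMAINS) cat(sprintf("  %-13s %d events\n", paste0(d, ":"), nrow(x$events[[d]])))
  cat("  coverage:", format(x$coverage_window[1]), "to",
      format(x$coverage_window[2]), "\n")
  invisible(x)
}

#' Number of patients in a dataset
#' @param dataset an `ehr_dataset`.
#' @return integer count.
#' @export
n_patients <- function(dataset) nrow(dataset$patients)

all_events <- function(dataset, domains = EVENT_DOMAINS) {
  bind_rows(lapply(dataset$events[domains], function(ev) {
    ev[, c("patient_id", "code_system", "code", "display", "event_date")]
  }), .id = "domain")
}

#' Validate a dataset against the data-model invariants
#'
#' Checks referential integrity (every event's `patient_id` exists in the
#' patients table), date sanity (no event before the patient's date of birth,
#' no event outside the coverage window), uniqueness of patient ids, and that
#' observation events carry values. Always returns a report; it never throws.
#'
#' @param dataset an `ehr_dataset`.
#' @return an object of class `dataset_validation`: a list with `counts`
#'   (per-table row counts and missingness) and `issues` (a tibble with
#'   columns `table`, `type`, `message`); `valid` is `TRUE` iff `issues`
#'   is empty.
#' @export
validate_dataset <- function(dataset) {
  issues <- list()
  add_issue <- function(table, type, message) {
    issues[[length(issues) + 1L]] <<- tibble(table = table, type = type, message = message)
  }

  p <- dataset$patients
  if (anyDuplicated(p$patient_id)) {
    dup <- unique(p$patient_id[duplicated(p$patient_id)])
    add_issue("patients", "duplicate_patient_id",
              paste("duplicated patient_id:", paste(dup, collapse = ", ")))
  }
  if (anyNA(p$date_of_birth)) add_issue("patients", "missing_dob", "missing date_of_birth")
  bad_sex <- setdiff(unique(p$sex), SEX_LEVELS)
  if (length(bad_sex)) {
    add_issue("patients", "invalid_sex",
              paste("sex values outside {female, male, other}:", paste(bad_sex, collapse = ", ")))
  }

  dob <- setNames(p$date_of_birth, p$patient_id)
  win <- dataset$coverage_window
  counts <- list(patients = tibble(table = "patients", rows = nrow(p),
                                   missing_values = sum(is.na(p))))
  for (d in EVENT_DOMAINS) {
    ev <- dataset$events[[d]]
    tab <- DOMAIN_TABLES[[d]]
    counts[[tab]] <- tibble(table = tab, rows = nrow(ev), missing_values = sum(is.na(ev)))
    if (nrow(ev) == 0L) next
    orphan <- setdiff(unique(ev$patient_id), p$patient_id)
    if (length(orphan)) {
      add_issue(tab, "orphan_patient_id",
                paste("event patient_id absent from patients:", paste(orphan, collapse = ", ")))
    }
    if (any(!nzchar(ev$code) | is.na(ev$code))) add_issue(tab, "empty_code", "empty or missing code")
    known <- ev$patient_id %in% p$patient_id
    before_birth <- known & ev$event_date < dob[ev$patient_id]
    if (any(before_birth, na.rm = TRUE)) {
      add_issue(tab, "event_before_birth",
                paste("events dated before date_of_birth for:",
                      paste(unique(ev$patient_id[which(before_birth)]), collapse = ", ")))
    }
    outside <- ev$event_date < win[1] | ev$event_date > win[2]
    if (any(outside, na.rm = TRUE)) {
      add_issue(tab, "event_outside_coverage",
                sprintf("%d event(s) outside the coverage window", sum(outside, na.rm = TRUE)))
    }
    if (d == "observation" && anyNA(ev$value)) {
      add_issue(tab, "missing_observation_value", "observation event(s) with no value")
    }
  }

  issues <- if (length(issues)) bind_rows(issues) else
    tibble(table = character(), type = character(), message = character())
  structure(
    list(counts = bind_rows(counts), issues = issues, valid = nrow(issues) == 0L),
    class = "dataset_validation"
  )
}

#' @export
print.dataset_validation <- function(x, ...) {
  cat("<dataset_validation>", if (x$valid) "OK" else paste(nrow(x$issues), "issue(s)"), "\n")
  print(x$counts)
  if (!x$valid) print(x$issues)
  invisible(x)
}

#' Write a dataset as Parquet tables
#'
#' Writes one Parquet file per domain plus the patients table and a
#' `metadata.json` sidecar holding the coverage window. Rows are sorted by
#' `(patient_id, event_date, code)` so repeated writes produce identical
#' logical tables.
#'
#' @param dataset an `ehr_dataset`.
#' @param path directory to write into (created if absent).
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(path)) abort(paste("cannot create directory:", path))
  arrow::write_parquet(dataset$patients, file.path(path, "patients.parquet"))
  for (d in EVENT_DOMAINS) {
    arrow::write_parquet(sort_events(dataset$events[[d]]),
                         file.path(path, paste0(DOMAIN_TABLES[[d]], ".parquet")))
  }
  jsonlite::write_json(
    list(coverage_window = format(dataset$coverage_window, "%Y-%m-%d")),
    file.path(path, "metadata.json"), auto_unbox = TRUE, pretty = TRUE
  )
  invisible(path)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param path directory containing `patients.parquet`, the four domain
#'   tables, and `metadata.json`.
#' @param validate if `TRUE` (default) run [validate_dataset()] and error on
#'   referential-integrity violations.
#' @return an `ehr_dataset`.
#' @export
read_dataset <- function(path, validate = TRUE) {
  if (!dir.exists(path)) abort(paste("dataset directory does not exist:", path))
  needed <- c("patients", unname(DOMAIN_TABLES))
  missing <- needed[!file.exists(file.path(path, paste0(needed, ".parquet")))]
  if (length(missing)) {
    abort(paste0("dataset at ", path, " is missing table(s): ",
                 paste(missing, collapse = ", ")))
  }
  meta_file <- file.path(path, "metadata.json")
  if (!file.exists(meta_file)) abort(paste("dataset is missing metadata.json sidecar:", path))
  meta <- jsonlite::read_json(meta_file, simplifyVector = TRUE)

  patients <- as_tibble(arrow::read_parquet(file.path(path, "patients.parquet")))
  events <- lapply(EVENT_DOMAINS, function(d) {
    as_tibble(arrow::read_parquet(file.path(path, paste0(DOMAIN_TABLES[[d]], ".parquet"))))
  })
  names(events) <- EVENT_DOMAINS
  ds <- ehr_dataset(patients, events, as.Date(meta$coverage_window))
  if (validate) {
    rep <- validate_dataset(ds)
    ri <- rep$issues[rep$issues$type == "orphan_patient_id", ]
    if (nrow(ri)) {
      abort(paste0("referential-integrity violation: ", paste(ri$message, collapse = "; ")))
    }
  }
  ds
}

#' Pseudonymize patient identifiers
#'
#' Replaces every `patient_id` with a keyed-hash pseudonym (16 hex
#' characters). The same `(id, salt)` pair always maps to the same pseudonym,
#' so re-runs are stable, while changing the salt revokes the whole mapping.
#' Collisions among the supplied ids are checked and rejected.
#'
#' @param dataset an `ehr_dataset` whose ids may be raw identifiers.
#' @param salt non-empty secret string; an empty salt is refused.
#' @return list with `dataset` (ids replaced everywhere) and `mapping`
#'   (tibble `raw_id`, `pseudonym`). Keep the mapping out of any shared
#'   output: it re-identifies the data.
#' @export
pseudonymize <- function(dataset, salt) {
  ids <- dataset$patients$patient_id
  pseud <- keyed_hash(ids, salt)
  if (anyDuplicated(pseud)) {
    abort("pseudonym collision detected; use a different salt")
  }
  map <- setNames(pseud, ids)
  patients <- dataset$patients
  patients$patient_id <- unname(map[patients$patient_id])
  events <- lapply(dataset$events, function(ev) {
    ev$patient_id <- unname(map[ev$patient_id])
    ev
  })
  list(
    dataset = ehr_dataset(patients, events, dataset$coverage_window),
    mapping = tibble(raw_id = ids, pseudonym = unname(pseud))
  )
}
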