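# Declarative computable-phenotype engine. A cohort definition is an ordered
# list of criteria over coded events; membership semantics:
#   * include criteria with role "index_candidate" define entry; the index
#     date is the earliest event matching any of them;
#   * every include criterion must be satisfied under its temporal clause
#     (AND across criteria; OR across the code prefixes within one);
#   * no exclude criterion may be satisfied under its temporal clause,
#     evaluated relative to the index date, with same-day ties counting as
#     "on_or_after" (date-resolution data cannot order same-day events, and
#     the conservative reading excludes more).

CRITERION_MODES <- c("include", "exclude")
CRITERION_TEMPORAL <- c("ever", "on_or_after_index", "before_index")
CRITERION_ROLES <- c("plain", "index_candidate")

#' Define one cohort criterion
#'
#' @param domain event domain (`diagnosis`, `procedure`, `medication`,
#'   `observation`).
#' @param code_prefix one or more code prefixes (normalized on input);
#'   alternatives within one criterion are OR-ed.
#' @param mode `"include"` or `"exclude"`.
#' @param temporal when the matching event must occur: `"ever"` (default),
#'   `"on_or_after_index"`, or `"before_index"`.
#' @param role `"index_candidate"` marks an include criterion whose earliest
#'   match defines cohort entry; `"plain"` otherwise.
#' @param code_system optional vocabulary restriction (e.g. `"ICD-10"`).
#' @return an object of class `criterion`.
#' @export
criterion <- function(domain, code_prefix, mode = "include",
                      temporal = "ever", role = "plain", code_system = NULL) {
  mode <- arg_match0(mode, CRITERION_MODES)
  temporal <- arg_match0(temporal, CRITERION_TEMPORAL)
  role <- arg_match0(role, CRITERION_ROLES)
  if (!domain %in% EVENT_DOMAINS) {
    abort(paste0("unknown domain `", domain, "`; expected one of: ",
                 paste(EVENT_DOMAINS, collapse = ", ")))
  }
  code_prefix <- normalize_code(code_prefix)
  if (length(code_prefix) == 0L || any(!nzchar(code_prefix))) {
    abort("`code_prefix` must contain at least one non-empty prefix")
  }
  if (role == "index_candidate" && mode != "include") {
    abort("an index_candidate criterion must have mode \"include\"")
  }
  structure(list(domain = domain, code_system = code_system,
                 code_prefix = code_prefix, mode = mode,
                 temporal = temporal, role = role),
            class = "criterion")
}

#' Define a cohort
#'
#' @param name cohort name.
#' @param criteria list of [criterion()]s; at least one include criterion
#'   with role `"index_candidate"` is required.
#' @return an object of class `cohort_definition`.
#' @export
cohort_definition <- function(name, criteria) {
  if (inherits(criteria, "criterion")) criteria <- list(criteria)
  stopifnot(all(vapply(criteria, inherits, logical(1), "criterion")))
  has_index <- any(vapply(criteria, function(cr) {
    cr$mode == "include" && cr$role == "index_candidate"
  }, logical(1)))
  if (!has_index) {
    abort("a cohort definition needs >= 1 include criterion with role \"index_candidate\"")
  }
  structure(list(name = name, criteria = criteria), class = "cohort_definition")
}

#' Parse a cohort definition from JSON
#'
#' The document layout (shipped as `inst/schema/cohort-definition-schema.json`)
#' is `{"name": ..., "criteria": [{"domain", "code_prefix", "mode",
#' "temporal", "role", "code_system"}, ...]}`. Codes are normalized; a
#' definition without an index-defining include criterion is rejected.
#' Errors carry a JSON-pointer-style path to the offending field.
#'
#' @param text JSON string, or the path of a JSON file.
#' @return a [cohort_definition()].
#' @export
parse_cohort_definition <- function(text) {
  if (length(text) == 1L && !grepl("[{[]", text) && file.exists(text)) {
    text <- paste(readLines(text, warn = FALSE), collapse = "\n")
  }
  doc <- tryCatch(jsonlite::fromJSON(text, simplifyVector = FALSE),
                  error = function(e) abort(paste("invalid JSON:", conditionMessage(e))))
  if (is.null(doc$name) || !is.character(doc$name %||% NULL)) {
    abort("cohort definition invalid at /name: expected a string")
  }
  if (is.null(doc$criteria) || !length(doc$criteria)) {
    abort("cohort definition invalid at /criteria: expected a non-empty array")
  }
  crits <- lapply(seq_along(doc$criteria), function(i) {
    c0 <- doc$criteria[[i]]
    at <- function(field) sprintf("/criteria/%d/%s", i - 1L, field)
    if (is.null(c0$domain)) abort(paste("cohort definition invalid at", at("domain"), ": required"))
    if (is.null(c0$code_prefix)) abort(paste("cohort definition invalid at", at("code_prefix"), ": required"))
    tryCatch(
      criterion(domain = c0$domain,
                code_prefix = unlist(c0$code_prefix),
                mode = c0$mode %||% "include",
                temporal = c0$temporal %||% "ever",
                role = c0$role %||% "plain",
                code_system = c0$code_system),
      error = function(e) abort(sprintf("cohort definition invalid at /criteria/%d: %s",
                                        i - 1L, conditionMessage(e)))
    )
  })
  cohort_definition(doc$name, crits)
}

#' Serialize a cohort definition to JSON
#' @param definition a [cohort_definition()].
#' @param path optional file to write to.
#' @return JSON string (invisibly if written to `path`).
#' @export
write_cohort_definition <- function(definition, path = NULL) {
  doc <- list(name = definition$name,
              criteria = lapply(definition$criteria, unclass))
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = TRUE, null = "null")
  if (!is.null(path)) {
    writeLines(json, path)
    return(invisible(json))
  }
  json
}

criterion_events <- function(dataset, cr) {
  ev <- dataset$events[[cr$domain]]
  if (!is.null(cr$code_system)) ev <- ev[ev$code_system %in% cr$code_system, ]
  ev[code_matches(ev$code, cr$code_prefix), c("patient_id", "event_date")]
}

temporal_ok <- function(dates, index_date, temporal) {
  switch(temporal,
    ever = rep(TRUE, length(dates)),
    on_or_after_index = dates >= index_date,
    before_index = dates < index_date
  )
}

#' Resolve a cohort definition against a dataset
#'
#' A patient is a member iff they have a qualifying index event (earliest
#' match across all index-candidate criteria becomes the index date), every
#' include criterion is met under its temporal clause relative to that index
#' date, and no exclude criterion is met under its clause. Same-day events
#' count as "on or after" the index.
#'
#' @param dataset an `ehr_dataset`.
#' @param definition a [cohort_definition()].
#' @return an object of class `cohort`: a tibble of `patient_id`,
#'   `index_date`, sorted by `patient_id`, with the definition name attached
#'   as attribute `cohort_name`.
#' @export
evaluate_cohort <- function(dataset, definition) {
  crits <- definition$criteria
  idx_crits <- Filter(function(cr) cr$role == "index_candidate", crits)

  idx_events <- bind_rows(lapply(idx_crits, criterion_events, dataset = dataset))
  if (nrow(idx_events) == 0L) {
    return(new_cohort(tibble(patient_id = character(),
                             index_date = as.Date(character())),
                      definition$name))
  }
  index <- idx_events %>%
    group_by(patient_id) %>%
    summarise(index_date = min(event_date), .groups = "drop")

  keep <- rep(TRUE, nrow(index))
  for (cr in crits) {
    if (cr$role == "index_candidate" && cr$temporal == "ever") next  # defines the index itself
    ev <- criterion_events(dataset, cr)
    sat <- vapply(seq_len(nrow(index)), function(k) {
      d <- ev$event_date[ev$patient_id == index$patient_id[k]]
      any(temporal_ok(d, index$index_date[k], cr$temporal))
    }, logical(1))
    keep <- keep & if (cr$mode == "include") sat else !sat
  }
  out <- index[keep, ]
  new_cohort(out[order(out$patient_id), ], definition$name)
}

new_cohort <- function(members, name) {
  structure(as_tibble(members), cohort_name = name,
            class = c("cohort", class(as_tibble(members))))
}

#' @export
print.cohort <- function(x, ...) {
  cat("<cohort>", attr(x, "cohort_name") %||% "", "-", nrow(x), "member(s)\n")
  NextMethod()
}

#' Cohort name
#' @param cohort a `cohort`.
#' @return character scalar.
#' @export
cohort_name <- function(cohort) attr(cohort, "cohort_name") %||% "cohort"

#' Read / write resolved cohorts as CSV
#'
#' Two columns, `patient_id` and `index_date` (ISO-8601).
#'
#' @param cohort a `cohort`.
#' @param path CSV file path.
#' @param name cohort name to attach on read.
#' @return `write_cohort` returns `path` invisibly; `read_cohort` a `cohort`.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(as_tibble(cohort)[, c("patient_id", "index_date")],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path, name = sub("\\.csv$", "", basename(path))) {
  df <- utils::read.csv(path, colClasses = c(patient_id = "character"))
  df$index_date <- as.Date(df$index_date)
  new_cohort(as_tibble(df), name)
}
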