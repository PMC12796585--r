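# Pipeline runner: cohort definition -> resolution -> analytics modules ->
# report bundle, deterministic given (dataset, config, seed), with per-stage
# structured logging and provenance (content hashes, seed, package version).

hash_tibble <- function(df) {
  s <- paste(vapply(df, function(col) paste(format(col), collapse = "\x1f"),
                    character(1)), collapse = "\x1e")
  fnv1a32(as.integer(charToRaw(s)))
}

#' Content hash of a dataset
#'
#' Order-independent of file layout: hashes the sorted logical tables.
#' Used in report provenance so archived outputs carry verifiable lineage.
#'
#' @param dataset an `ehr_dataset`.
#' @return 8-hex-character string.
#' @export
dataset_hash <- function(dataset) {
  h <- hash_tibble(dataset$patients)
  for (d in EVENT_DOMAINS) {
    h <- xor32(mul_mod32(h, FNV_PRIME_32), hash_tibble(dataset$events[[d]]))
  }
  hex32(h)
}

resolve_definition <- function(x) {
  if (inherits(x, "cohort_definition")) return(x)
  if (is.character(x) && length(x) == 1L) return(parse_cohort_definition(x))
  if (is.list(x)) return(parse_cohort_definition(jsonlite::toJSON(x, auto_unbox = TRUE)))
  abort("cannot interpret cohort definition entry")
}

#' Run an analytics pipeline
#'
#' Stages: load (or accept) the dataset, resolve every cohort definition,
#' then run each configured module in order. Any stage failure marks the
#' bundle `failed` with that stage's error while preserving the outputs of
#' prior stages. Output is a pure function of (dataset, config, seed).
#'
#' @param config a list (or path to a YAML file) with fields:
#'   `title`; `data` (dataset directory, or an `ehr_dataset` passed
#'   directly); `cohorts` — list of cohort definitions (objects, JSON
#'   strings/paths, or inline lists); `steps` — list of
#'   `list(module =, cohorts = <names>, params = list(...))`;
#'   optional `seed` and `threshold` (suppression, default 5).
#' @return an object of class `report_bundle`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) config <- yaml::read_yaml(config)
  if (is.null(config$steps) || !length(config$steps)) {
    abort("pipeline config needs at least one step in `steps`")
  }
  if (is.null(config$cohorts) || !length(config$cohorts)) {
    abort("pipeline config needs at least one cohort definition in `cohorts`")
  }
  seed <- config$seed %||% 1L
  threshold <- config$threshold %||% 5
  log <- list()
  note <- function(stage, msg) {
    log[[length(log) + 1L]] <<- list(stage = stage, message = msg)
  }

  bundle <- structure(
    list(title = config$title %||% "analytics report", status = "ok",
         error = NULL, definitions = list(), cohorts = list(),
         results = list(), threshold = threshold, log = NULL,
         provenance = NULL),
    class = "report_bundle"
  )
  fail <- function(stage, e) {
    bundle$status <<- "failed"
    bundle$error <<- list(stage = stage, message = conditionMessage(e))
    note(stage, paste("FAILED:", conditionMessage(e)))
  }

  dataset <- tryCatch({
    ds <- if (inherits(config$data, "ehr_dataset")) config$data else read_dataset(config$data)
    note("provision", sprintf("dataset: %d patients, hash %s",
                              n_patients(ds), dataset_hash(ds)))
    ds
  }, error = function(e) { fail("provision", e); NULL })

  if (!is.null(dataset)) {
    for (entry in config$cohorts) {
      res <- tryCatch({
        def <- resolve_definition(entry)
        co <- evaluate_cohort(dataset, def)
        note("cohort", sprintf("\"%s\": %d member(s)", def$name, nrow(co)))
        bundle$definitions[[def$name]] <- def
        bundle$cohorts[[def$name]] <- co
        TRUE
      }, error = function(e) { fail("cohort", e); FALSE })
      if (!res) break
    }
  }

  if (bundle$status == "ok") {
    for (i in seq_along(config$steps)) {
      step <- config$steps[[i]]
      label <- step$label %||% paste0(step$module, "_", i)
      ok <- tryCatch({
        mod <- get_module(step$module)
        wanted <- unlist(step$cohorts) %||% names(bundle$cohorts)
        missing <- setdiff(wanted, names(bundle$cohorts))
        if (length(missing)) {
          abort(paste0("step references undefined cohort(s): ",
                       paste(missing, collapse = ", ")))
        }
        params <- step$params %||% list()
        params$threshold <- params$threshold %||% threshold
        set.seed(derive_seed(seed, label))
        out <- mod$fun(dataset, bundle$cohorts[wanted], params)
        bundle$results[[label]] <- list(module = step$module,
                                        spec = mod$spec,
                                        cohorts = wanted, params = params,
                                        output = out)
        note("analysis", sprintf("%s (%s): ok", label, step$module))
        TRUE
      }, error = function(e) { fail(paste0("analysis:", label), e); FALSE })
      if (!ok) break
    }
  }

  cfg_for_hash <- config
  if (inherits(cfg_for_hash$data, "ehr_dataset")) {
    cfg_for_hash$data <- if (is.null(dataset)) "inline" else dataset_hash(dataset)
  }
  bundle$log <- log
  bundle$provenance <- list(
    dataset_hash = if (!is.null(dataset)) dataset_hash(dataset) else NA_character_,
    config_hash = hex32(fnv1a32(as.integer(charToRaw(
      jsonlite::toJSON(cfg_for_hash, auto_unbox = TRUE, force = TRUE, digits = NA))))),
    seed = seed,
    package_version = as.character(packageVersion("ehrconsult")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  )
  bundle
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("<report_bundle>", x$title, "-", x$status, "\n")
  cat("  cohorts:", paste(sprintf("%s (n=%d)", names(x$cohorts),
                                  vapply(x$cohorts, nrow, integer(1))),
                          collapse = ", "), "\n")
  cat("  results:", paste(names(x$results), collapse = ", "), "\n")
  if (!is.null(x$error)) cat("  error at", x$error$stage, ":", x$error$message, "\n")
  invisible(x)
}

#' Canonical JSON serialization of a report bundle
#'
#' Timestamps can be excluded so that two runs of the same pipeline with the
#' same seed serialize identically.
#'
#' @param bundle a `report_bundle`.
#' @param include_timestamp keep the provenance timestamp (default `FALSE`).
#' @return JSON string.
#' @export
bundle_json <- function(bundle, include_timestamp = FALSE) {
  prov <- bundle$provenance
  if (!include_timestamp) prov$timestamp <- NULL
  results <- lapply(bundle$results, function(r) {
    out <- r$output
    ser <- if (inherits(out, "result_table")) {
      list(type = "result_table", threshold = attr(out, "threshold"),
           columns = as.list(as_tibble(out)), suppressed = attr(out, "suppressed"))
    } else if (inherits(out, "rr_scan")) {
      list(type = "rr_scan", columns = as.list(as_tibble(out)))
    } else if (inherits(out, "age_comparison")) {
      list(type = "age_comparison", summaries = as.list(out$summaries),
           kw = out$kw[c("H", "df", "p")])
    } else if (inherits(out, "consult_report")) {
      list(type = "consult_report", patient_id = out$patient_id,
           scores = as.list(out$scores), n = out$n)
    } else if (is.list(out) && !is.null(out$summary)) {
      list(type = "tte_result",
           summary = list(median = out$summary$median,
                          median_reached = out$summary$median_reached,
                          incidence = as.list(out$summary$incidence)),
           curve = as.list(as_tibble(out$curve)))
    } else {
      list(type = class(out)[1])
    }
    c(list(module = r$module, cohorts = r$cohorts), ser)
  })
  jsonlite::toJSON(
    list(title = bundle$title, status = bundle$status, error = bundle$error,
         cohorts = lapply(bundle$cohorts, function(co) {
           list(name = cohort_name(co), n = nrow(co),
                members = as.list(as_tibble(co)))
         }),
         results = results, provenance = prov),
    auto_unbox = TRUE, pretty = TRUE, digits = NA, null = "null", force = TRUE
  )
}
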