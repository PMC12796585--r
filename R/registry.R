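# Analytics-module registry. Every analytics capability is invoked through a
# registered module with a declared contract — named inputs drawn from the
# common data model, one declared output type — so a pipeline config can
# only call modules whose interfaces are known, and new analytics enter the
# library as self-contained registered units rather than ad-hoc code.

MODULE_INPUT_TYPES <- c("dataset", "cohort", "cohort_list", "params")
MODULE_OUTPUT_TYPES <- c("result_table", "rr_scan", "age_comparison",
                         "tte_result", "consult_report")

.registry <- new.env(parent = emptyenv())

#' Declare an analytics module
#'
#' @param name unique module name.
#' @param version module version string; `name@version` must be unique in
#'   the registry.
#' @param inputs character vector of declared input types; allowed values
#'   are `"dataset"`, `"cohort"`, `"cohort_list"`, `"params"`.
#' @param output declared output type: one of `"result_table"`, `"rr_scan"`,
#'   `"age_comparison"`, `"tte_result"`, `"consult_report"`.
#' @param description one-line documentation string.
#' @return an object of class `analytics_module_spec`.
#' @export
analytics_module_spec <- function(name, version, inputs, output, description = "") {
  bad <- setdiff(inputs, MODULE_INPUT_TYPES)
  if (length(bad)) {
    abort(paste0("unknown input type(s): ", paste(bad, collapse = ", "),
                 "; allowed: ", paste(MODULE_INPUT_TYPES, collapse = ", ")))
  }
  if (!output %in% MODULE_OUTPUT_TYPES) {
    abort(paste0("unknown output type `", output, "`; allowed: ",
                 paste(MODULE_OUTPUT_TYPES, collapse = ", ")))
  }
  structure(list(name = name, version = version, inputs = inputs,
                 output = output, description = description),
            class = "analytics_module_spec")
}

#' Register an analytics module
#'
#' The implementation must be a function with the signature
#' `function(dataset, cohorts, params)` where `cohorts` is a named list of
#' resolved cohorts and `params` a list of module parameters; it must return
#' the declared output type. A duplicate `name@version` or a signature
#' mismatch is rejected.
#'
#' @param spec an [analytics_module_spec()].
#' @param implementation conforming function.
#' @return the registry key (`name@version`), invisibly.
#' @export
register_module <- function(spec, implementation) {
  stopifnot(inherits(spec, "analytics_module_spec"))
  if (!is.function(implementation)) abort("`implementation` must be a function")
  fa <- names(formals(implementation))
  if (!identical(fa[1:3], c("dataset", "cohorts", "params"))) {
    abort(paste0("implementation signature mismatch: expected ",
                 "function(dataset, cohorts, params), got function(",
                 paste(fa, collapse = ", "), ")"))
  }
  key <- paste0(spec$name, "@", spec$version)
  if (exists(key, envir = .registry, inherits = FALSE)) {
    abort(paste0("module `", key, "` is already registered"))
  }
  assign(key, list(spec = spec, fun = implementation), envir = .registry)
  invisible(key)
}

#' List registered analytics modules
#' @return tibble with columns `name`, `version`, `inputs`, `output`,
#'   `description`.
#' @export
list_modules <- function() {
  keys <- sort(ls(.registry))
  bind_rows(lapply(keys, function(k) {
    s <- get(k, envir = .registry)$spec
    tibble(name = s$name, version = s$version,
           inputs = paste(s$inputs, collapse = ","),
           output = s$output, description = s$description)
  }))
}

get_module <- function(name, version = NULL) {
  keys <- ls(.registry)
  hits <- keys[sub("@.*$", "", keys) == name]
  if (!is.null(version)) hits <- hits[hits == paste0(name, "@", version)]
  if (!length(hits)) abort(paste0("no registered module named `", name, "`"))
  get(sort(hits, decreasing = TRUE)[1], envir = .registry)
}

register_builtin_modules <- function() {
  reg <- function(name, inputs, output, desc, fun) {
    key <- paste0(name, "@", "1.0")
    if (exists(key, envir = .registry, inherits = FALSE)) return(invisible())
    register_module(analytics_module_spec(name, "1.0", inputs, output, desc), fun)
  }
  reg("demographics", c("dataset", "cohort_list"), "result_table",
      "Per-cohort demographics overview with small-cell suppression",
      function(dataset, cohorts, params) {
        demographics_overview(dataset, cohorts, threshold = params$threshold %||% 5)
      })
  reg("frequency", c("dataset", "cohort", "params"), "result_table",
      "Percentage of cohort members with at least one matching event",
      function(dataset, cohorts, params) {
        frequency_analysis(dataset, cohorts[[1]],
                           domain = params$domain %||% "medication",
                           group_by = params$group_by %||% "generic_name",
                           window = params$window %||% "after_index",
                           top_k = params$top_k %||% 15,
                           threshold = params$threshold %||% 5)
      })
  reg("relative_risk_scan", c("dataset", "cohort_list", "params"), "rr_scan",
      "Relative risk of code categories, exposed vs comparator cohort",
      function(dataset, cohorts, params) {
        relative_risk_scan(dataset, cohorts[[1]], cohorts[[2]],
                           domain = params$domain %||% "diagnosis",
                           exclude_prefixes = params$exclude_prefixes %||% character(),
                           top_k = params$top_k %||% 10,
                           alpha = params$alpha %||% 0.05,
                           code_level = params$code_level %||% 3L)
      })
  reg("age_comparison", c("dataset", "cohort_list"), "age_comparison",
      "Age-at-entry summaries, density curves and Kruskal-Wallis test",
      function(dataset, cohorts, params) {
        age_at_entry_comparison(dataset, cohorts, bw = params$bw %||% "nrd0")
      })
  reg("time_to_event", c("dataset", "cohort", "params"), "tte_result",
      "Time from index to first target event, product-limit summary",
      function(dataset, cohorts, params) {
        target <- criterion(params$target_domain %||% "procedure",
                            params$target_code,
                            code_system = params$target_code_system)
        rec <- time_to_first_event(dataset, cohorts[[1]], target,
                                   horizon = params$horizon %||% 28)
        curve <- kaplan_meier(rec)
        list(records = rec, curve = curve,
             summary = tte_summary(curve, params$days_of_interest %||% c(3, 7, 14, 28)))
      })
  reg("consult", c("dataset", "cohort_list", "params"), "consult_report",
      "Individual-patient z-scores/centiles against a comparator reference model",
      function(dataset, cohorts, params) {
        consult(dataset, cohorts[[1]], cohorts[[2]],
                observation_code = params$observation_code,
                window = params$window %||% c(7, 730),
                smooth = params$smooth %||% smooth_spec())
      })
  invisible()
}

.onLoad <- function(libname, pkgname) {
  register_builtin_modules()
}
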