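pipeline_config <- function(data, seed = 1, extra_steps = list()) {
  list(
    title = "test report", data = data, seed = seed, threshold = 5,
    cohorts = list(
      jsonlite::fromJSON(example_definition_json("dialysis"),
                         simplifyVector = FALSE),
      jsonlite::fromJSON(example_definition_json("transplant_success"),
                         simplifyVector = FALSE)
    ),
    steps = c(list(
      list(module = "demographics", label = "demo"),
      list(module = "frequency", label = "meds", cohorts = "Dialysis Patients",
           params = list(domain = "medication", group_by = "generic_name",
                         top_k = 15))
    ), extra_steps)
  )
}

test_that("registry enforces the module contract", {
  spec <- analytics_module_spec("toy_counter", "0.1", c("dataset", "cohort"),
                                "result_table", "counts things")
  key <- register_module(spec, function(dataset, cohorts, params) {
    result_table(tibble::tibble(label = "n", count = nrow(cohorts[[1]]),
                                pct = NA_real_),
                 count_cols = "count")
  })
  expect_true("toy_counter" %in% list_modules()$name)
  # duplicate name@version rejected
  expect_error(register_module(spec, function(dataset, cohorts, params) NULL),
               "already registered")
  # unknown input type rejected at spec construction
  expect_error(analytics_module_spec("bad", "1", "warehouse", "result_table"),
               "unknown input type")
  expect_error(analytics_module_spec("bad", "1", "dataset", "hologram"),
               "unknown output type")
  # signature mismatch rejected
  expect_error(register_module(
    analytics_module_spec("toy2", "1", "dataset", "result_table"),
    function(x, y) NULL), "signature mismatch")
  # built-ins present
  expect_true(all(c("demographics", "frequency", "relative_risk_scan",
                    "age_comparison", "time_to_event", "consult") %in%
                    list_modules()$name))
})

test_that("a pipeline run is deterministic and reproducible from disk", {
  sim <- simulate_dataset(make_example_scenario("dialysis_meds",
                                                n_patients = 60, seed = 8))
  dir <- withr::local_tempdir()
  write_dataset(sim$dataset, dir)
  cfg <- pipeline_config(dir, seed = 11)
  b1 <- run_pipeline(cfg)
  b2 <- run_pipeline(cfg)
  expect_identical(b1$status, "ok")
  expect_identical(bundle_json(b1), bundle_json(b2))
  expect_match(b1$provenance$dataset_hash, "^[0-9a-f]{8}$")
  # the 15-row medication table mirrors the frequency workload
  expect_lte(nrow(b1$results$meds$output), 15)
})

test_that("stage failures mark the bundle failed but keep earlier outputs", {
  sim <- simulate_dataset(make_example_scenario("dialysis_meds",
                                                n_patients = 40, seed = 9))
  cfg <- pipeline_config(sim$dataset,
                         extra_steps = list(list(module = "does_not_exist",
                                                 label = "boom")))
  b <- run_pipeline(cfg)
  expect_identical(b$status, "failed")
  expect_match(b$error$message, "does_not_exist")
  expect_true(all(c("demo", "meds") %in% names(b$results)))
  f <- withr::local_tempfile(fileext = ".html")
  render_report(b, f)
  expect_match(paste(readLines(f), collapse = ""), "Pipeline failed")
})

test_that("rendered reports mask small counts and refuse unknown formats", {
  sim <- simulate_dataset(make_example_scenario("dialysis_meds",
                                                n_patients = 25, seed = 10))
  cfg <- pipeline_config(sim$dataset)
  b <- run_pipeline(cfg)
  f <- withr::local_tempfile(fileext = ".html")
  render_report(b, f)
  expect_length(scan_report_counts(f, 5), 0)
  html <- paste(readLines(f), collapse = "\n")
  expect_match(html, "not causal")          # fixed disclaimer
  expect_match(html, b$provenance$config_hash)  # provenance footer
  fp <- withr::local_tempfile(fileext = ".html")
  render_report(b, fp, format = "print")
  expect_match(paste(readLines(fp), collapse = ""), "@media print", fixed = TRUE)
  expect_error(render_report(b, f, format = "docx"), "unsupported")
})

test_that("the CLI surface drives simulate, build-cohort and analyze", {
  dir <- withr::local_tempdir()
  cfgf <- file.path(dir, "sim.yaml")
  write_sim_config(make_example_scenario("dialysis_meds", n_patients = 30,
                                         seed = 13), cfgf)
  out <- file.path(dir, "data")
  expect_output(cli_main(c("simulate", "--config", cfgf, "--out", out)),
                "30 patients")
  deff <- file.path(dir, "def.json")
  writeLines(example_definition_json("dialysis"), deff)
  cof <- file.path(dir, "cohort.csv")
  expect_output(cli_main(c("build-cohort", "--data", out, "--definition", deff,
                           "--out", cof)), "member")
  resf <- file.path(dir, "freq.csv")
  expect_output(cli_main(c("analyze", "frequency", "--data", out,
                           "--cohort", cof, "--out", resf,
                           "--params", '{"domain":"medication","group_by":"generic_name","top_k":5}')),
                "freq.csv")
  expect_true(file.exists(resf))
  expect_output(cli_main("list-modules"), "frequency")
})

test_that("figure builders return ggplot objects", {
  sim <- simulate_dataset(make_example_scenario("dialysis_meds",
                                                n_patients = 40, seed = 14))
  co <- evaluate_cohort(sim$dataset, parse_cohort_definition(
    example_definition_json("dialysis")))
  tab <- frequency_analysis(sim$dataset, co, "medication", "generic_name",
                            top_k = 5)
  expect_s3_class(plot_frequency(tab), "ggplot")
  rec <- tibble::tibble(patient_id = as.character(1:4), time = c(1, 2, 3, 4),
                        event = c(TRUE, FALSE, TRUE, TRUE))
  expect_s3_class(plot_survival_curve(kaplan_meier(rec)), "ggplot")
})
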