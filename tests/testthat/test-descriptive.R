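test_that("suppression masks exactly the counts in 1..threshold-1", {
  tab <- result_table(tibble::tibble(label = letters[1:4],
                                     count = c(0, 3, 5, 12),
                                     pct = c(0, 15, 25, 60)),
                      count_cols = "count", pct_map = c(count = "pct"))
  sup <- suppress_small_counts(tab, 5)
  expect_equal(sup$count, c(0, NA, 5, 12))
  expect_equal(sup$pct, c(0, NA, 25, 60))
  fm <- format(sup)
  expect_identical(fm$count[2], "<5")
  expect_identical(fm$pct[2], "<5")
  # idempotent
  sup2 <- suppress_small_counts(sup, 5)
  expect_identical(as.data.frame(sup2), as.data.frame(sup))
  # monotone in threshold: re-applying a higher threshold masks more, never less
  sup10 <- suppress_small_counts(sup, 10)
  expect_equal(sup10$count, c(0, NA, NA, 12))
  # threshold 1 masks nothing
  none <- suppress_small_counts(tab, 1)
  expect_equal(none$count, c(0, 3, 5, 12))
})

test_that("demographics overview counts, percentages and ages are right", {
  patients <- tibble::tibble(
    patient_id = sprintf("P%02d", 1:10),
    date_of_birth = as.Date("2000-01-01"),
    sex = c(rep("female", 6), rep("male", 4))
  )
  ds <- ehr_dataset(patients, list(), as.Date(c("2009-01-01", "2012-01-01")))
  co <- make_cohort(patients$patient_id, rep("2010-01-01", 10), "ten")
  tab <- demographics_overview(ds, list(co), threshold = 5)
  df <- tibble::as_tibble(tab)
  expect_equal(df$count[df$statistic == "sex_female"], 6)
  expect_equal(df$pct[df$statistic == "sex_female"], 60)
  # sex_male = 4 is below threshold 5 -> masked, rendered as "<5"
  expect_true(is.na(df$count[df$statistic == "sex_male"]))
  expect_identical(format(tab)$count[df$statistic == "sex_male"], "<5")
  # age at entry: 2000-01-01 -> 2010-01-01 is 3653 days = 10.0014 years
  expect_equal(df$value[df$statistic == "age_entry_median_years"],
               3653 / 365.25, tolerance = 1e-10)
})

test_that("a zero-member cohort yields empty cells, not an error", {
  ds <- tiny_dataset()
  co <- make_cohort(character(), as.Date(character()), "empty")
  tab <- demographics_overview(ds, list(co))
  expect_s3_class(tab, "result_table")
  expect_equal(tibble::as_tibble(tab)$count[1], 0)
})

test_that("frequency analysis counts patients, not events, in the window", {
  patients <- tibble::tibble(
    patient_id = paste0("P", 1:4), date_of_birth = as.Date("2010-01-01"),
    sex = "female"
  )
  meds <- tibble::tibble(
    patient_id = c("P1", "P2", "P3", "P4", rep("P1", 50)),
    code_system = "generic_name",
    code = c("DRUGA", "DRUGA", "DRUGA", "DRUGA", rep("DRUGB", 50)),
    display = c(rep("drug a", 4), rep("drug b", 50)),
    event_date = as.Date(c("2022-02-01", "2022-02-01", "2022-02-01",
                           "2021-12-01", rep("2022-03-01", 50)))
  )
  ds <- ehr_dataset(patients, list(medication = meds), WIN)
  co <- make_cohort(paste0("P", 1:4), rep("2022-01-01", 4), "m")
  tab <- frequency_analysis(ds, co, "medication", "generic_name",
                            window = "after_index", threshold = 1)
  df <- tibble::as_tibble(tab)
  # drug A after index for 3 of 4 (P4 only before index) -> 75%
  expect_equal(df$pct[df$label == "drug a"], 75)
  # 50 repeats of drug B by one patient contribute one patient
  expect_equal(df$count[df$label == "drug b"], 1)
  expect_equal(df$pct[df$label == "drug b"], 25)
  # duplicating an event never changes a frequency
  ds2 <- ds
  ds2$events$medication <- dplyr::bind_rows(ds2$events$medication,
                                            ds2$events$medication[1, ])
  tab2 <- frequency_analysis(ds2, co, "medication", "generic_name",
                             window = "after_index", threshold = 1)
  expect_equal(tibble::as_tibble(tab2)$pct, df$pct)
  expect_true(all(df$pct <= 100))
})

test_that("frequency ranking is deterministic and top_k is a prefix", {
  sim <- simulate_dataset(make_example_scenario("dialysis_meds",
                                                n_patients = 60, seed = 12))
  co <- evaluate_cohort(sim$dataset,
                        parse_cohort_definition(example_definition_json("dialysis")))
  full <- frequency_analysis(sim$dataset, co, "medication", "generic_name")
  top5 <- frequency_analysis(sim$dataset, co, "medication", "generic_name",
                             top_k = 5)
  expect_identical(tibble::as_tibble(top5),
                   head(tibble::as_tibble(full), 5))
  expect_error(frequency_analysis(sim$dataset, co, "medication", "potion"),
               "group_by")
})

test_that("the dialysis scenario reproduces its configured heparin frequency", {
  sim <- simulate_dataset(make_example_scenario("dialysis_meds",
                                                n_patients = 1250, seed = 31))
  co <- evaluate_cohort(sim$dataset,
                        parse_cohort_definition(example_definition_json("dialysis")))
  expect_gt(nrow(co), 900)
  tab <- frequency_analysis(sim$dataset, co, "medication", "generic_name",
                            top_k = 15)
  df <- tibble::as_tibble(tab)
  expect_identical(df$label[1], "heparin")
  expect_lt(abs(df$pct[1] / 100 - 0.96), 0.02)
})
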