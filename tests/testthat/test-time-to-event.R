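test_that("durations measure days from index, with same-day events at time 0", {
  patients <- tibble::tibble(patient_id = paste0("P", 1:3),
                             date_of_birth = as.Date("2015-01-01"),
                             sex = "male")
  proc <- tibble::tibble(
    patient_id = c("P1", "P2"),
    code_system = "OPCS-4", code = "U20", display = "echo",
    event_date = as.Date(c("2022-01-01", "2022-01-11"))
  )
  ds <- ehr_dataset(patients, list(procedure = proc), WIN)
  co <- make_cohort(paste0("P", 1:3), rep("2022-01-01", 3), "c")
  rec <- time_to_first_event(ds, co, criterion("procedure", "U20"), horizon = 28)
  expect_equal(rec$time[rec$patient_id == "P1"], 0)
  expect_true(rec$event[rec$patient_id == "P1"])
  expect_equal(rec$time[rec$patient_id == "P2"], 10)
  # P3 has no echo: censored at the 28-day horizon
  expect_equal(rec$time[rec$patient_id == "P3"], 28)
  expect_false(rec$event[rec$patient_id == "P3"])
  # censoring at coverage end when it comes before the horizon
  co_late <- make_cohort("P3", WIN[2] - 10, "late")
  rec2 <- time_to_first_event(ds, co_late, criterion("procedure", "U20"), horizon = 28)
  expect_equal(rec2$time, 10)
  expect_error(time_to_first_event(ds, co, criterion("procedure", "U20"),
                                   horizon = 0), "positive")
})

test_that("Kaplan-Meier reproduces the hand product-limit on {1, 2+, 3, 4}", {
  rec <- tibble::tibble(patient_id = paste0("x", 1:4),
                        time = c(1, 2, 3, 4),
                        event = c(TRUE, FALSE, TRUE, TRUE))
  km <- kaplan_meier(rec)
  expect_equal(km$time, c(1, 3, 4))
  expect_equal(km$surv, c(0.75, 0.375, 0), tolerance = 1e-15)
  expect_equal(surv_at(km, c(0.5, 1, 2.9, 3.5, 10)),
               c(1, 0.75, 0.75, 0.375, 0))
  # all censored -> S stays 1
  all_c <- tibble::tibble(patient_id = "a", time = 5, event = FALSE)
  expect_equal(surv_at(kaplan_meier(all_c), c(0, 10)), c(1, 1))
  expect_error(kaplan_meier(tibble::tibble(patient_id = "a", time = -1,
                                           event = TRUE)), "non-negative")
})

test_that("without censoring 1 - S is exactly the empirical CDF", {
  set.seed(14)
  for (i in 1:10) {
    t <- sample(0:30, 40, replace = TRUE)
    km <- kaplan_meier(tibble::tibble(patient_id = as.character(1:40),
                                      time = t, event = TRUE))
    grid <- 0:31
    expect_equal(1 - surv_at(km, grid), ecdf(t)(grid), tolerance = 1e-12)
  }
})

test_that("Kaplan-Meier matches the survival package to 1e-10 on censored data", {
  set.seed(66)
  for (i in 1:100) {
    n <- sample(5:60, 1)
    t <- sample(1:20, n, replace = TRUE)
    e <- runif(n) < 0.7
    if (!any(e)) e[1] <- TRUE
    km <- kaplan_meier(tibble::tibble(patient_id = as.character(1:n),
                                      time = t, event = e))
    sf <- survival::survfit(survival::Surv(t, e) ~ 1)
    ref_s <- summary(sf, times = km$time)$surv
    expect_equal(km$surv, ref_s, tolerance = 1e-10)
  }
})

test_that("censoring times beyond the last event are interchangeable", {
  # S depends on a late censored record only through its position relative to
  # the event times, not its exact value
  rec <- tibble::tibble(patient_id = paste0("x", 1:4),
                        time = c(1, 2, 3, 4), event = c(TRUE, FALSE, TRUE, TRUE))
  km_a <- kaplan_meier(dplyr::bind_rows(rec,
    tibble::tibble(patient_id = "x5", time = 5, event = FALSE)))
  km_b <- kaplan_meier(dplyr::bind_rows(rec,
    tibble::tibble(patient_id = "x5", time = 99, event = FALSE)))
  expect_equal(km_a$surv, km_b$surv, tolerance = 1e-15)
  expect_equal(km_a$time, km_b$time)
})

test_that("median and cumulative incidence summaries are right", {
  km <- kaplan_meier(tibble::tibble(patient_id = as.character(1:4),
                                    time = c(1, 3, 3, 10), event = TRUE))
  expect_equal(surv_at(km, 3), 0.25)
  s <- tte_summary(km, days_of_interest = c(3, 10))
  expect_equal(s$median, 3)
  expect_equal(s$incidence$cum_incidence, c(0.75, 1))
  # never crosses 0.5 -> not reached
  km2 <- kaplan_meier(tibble::tibble(patient_id = as.character(1:4),
                                     time = c(1, 5, 5, 5),
                                     event = c(TRUE, FALSE, FALSE, FALSE)))
  s2 <- tte_summary(km2)
  expect_false(s2$median_reached)
  expect_true(is.na(s2$median))
})

test_that("an exponential waiting time is recovered from a synthetic scenario", {
  cfg <- sim_config(
    n_patients = 1000, seed = 40, coverage_window = WIN,
    groups = list(group_spec("g", 1,
      panel = code_panel("procedure", "OPCS-4", "U20", "echo", 1,
                         wait_dist = "exponential", wait_scale = 3))),
    index_event = list(domain = "procedure", code_system = "OPCS-4",
                       code = "K11", display = "repair")
  )
  sim <- simulate_dataset(cfg)
  co <- evaluate_cohort(sim$dataset, parse_cohort_definition(
    example_definition_json("defect_repair")))
  rec <- time_to_first_event(sim$dataset, co, criterion("procedure", "U20"),
                             horizon = 28)
  km <- kaplan_meier(rec)
  s <- tte_summary(km)
  expect_lt(abs(s$median - 3 * log(2)), 0.3)
})
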