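test_that("relative risk matches the Katz closed form", {
  est <- relative_risk(4, 10, 2, 20)
  expect_equal(est$rr, 4.0, tolerance = 1e-15)
  # hand computation: exp(log 4 +/- qnorm(.975) * sqrt(1/4 - 1/10 + 1/2 - 1/20))
  se <- sqrt(0.6)
  expect_equal(est$ci_low, 4 * exp(-qnorm(0.975) * se), tolerance = 1e-12)
  expect_equal(est$ci_high, 4 * exp(qnorm(0.975) * se), tolerance = 1e-12)
  expect_equal(est$ci_low, 0.8764, tolerance = 1e-3)
  expect_equal(est$ci_high, 18.256, tolerance = 1e-3)
  expect_false(est$corrected)

  expect_equal(relative_risk(10, 10, 20, 20)$rr, 1.0)
  zero <- relative_risk(3, 10, 0, 20)
  expect_true(zero$corrected)
  expect_equal(zero$rr, (3.5 / 11) / (0.5 / 21), tolerance = 1e-12)
  expect_true(zero$ci_low <= zero$rr && zero$rr <= zero$ci_high)
  expect_error(relative_risk(1, 0, 1, 5), "positive")
})

test_that("95% Katz intervals cover a true RR of 2 at the nominal rate", {
  set.seed(2024)
  n <- 500; p2 <- 0.1; p1 <- 0.2  # true RR = 2
  hits <- vapply(1:2000, function(i) {
    a <- rbinom(1, n, p1); b <- rbinom(1, n, p2)
    est <- relative_risk(a, n, b, n)
    est$ci_low <= 2 && 2 <= est$ci_high
  }, logical(1))
  expect_lt(abs(mean(hits) - 0.95), 0.015)
})

test_that("the comorbidity scan excludes the defining code and ranks by RR", {
  patients <- tibble::tibble(patient_id = sprintf("P%02d", 1:30),
                             date_of_birth = as.Date("2010-01-01"),
                             sex = "female")
  # exposed P01..P10: everyone has S25; half of comparator P11..P30 has S25
  dx <- tibble::tibble(
    patient_id = c(sprintf("P%02d", 1:10), sprintf("P%02d", 11:20),
                   sprintf("P%02d", 1:10)),
    code_system = "ICD-10",
    code = c(rep("S251", 10), rep("S252", 10), rep("J90", 10)),
    display = "x", event_date = as.Date("2022-01-01")
  )
  ds <- ehr_dataset(patients, list(diagnosis = dx), WIN)
  exposed <- make_cohort(sprintf("P%02d", 1:10), rep("2021-12-01", 10), "exp")
  comparator <- make_cohort(sprintf("P%02d", 11:30), rep("2021-12-01", 20), "cmp")
  scan <- relative_risk_scan(ds, exposed, comparator,
                             exclude_prefixes = "J90", top_k = 10)
  expect_false("J90" %in% scan$code)
  expect_equal(scan$rr[scan$code == "S25"], 2.0)  # 10/10 vs 10/20, 3-char level
  expect_equal(scan$a[scan$code == "S25"], 10)
  # overlapping cohorts are ill-posed
  expect_error(relative_risk_scan(ds, exposed, exposed), "overlap")
  # permutation invariance of the input rows
  ds2 <- ds
  ds2$events$diagnosis <- ds$events$diagnosis[sample(nrow(dx)), ]
  scan2 <- relative_risk_scan(ehr_dataset(patients, list(diagnosis = ds2$events$diagnosis), WIN),
                              exposed, comparator, exclude_prefixes = "J90")
  expect_equal(tibble::as_tibble(scan2), tibble::as_tibble(scan))
})

test_that("scan point estimates for a true risk ratio of 3 fall inside their CIs", {
  # patient-level 2x2 sampling at the scan's counting rule, 500 replicates
  set.seed(55)
  n <- 800
  hits <- vapply(1:500, function(i) {
    est <- relative_risk(rbinom(1, n, 0.30), n, rbinom(1, n, 0.10), n)
    est$ci_low <= 3 && 3 <= est$ci_high
  }, logical(1))
  expect_gte(mean(hits), 0.93)
})

test_that("Kruskal-Wallis reproduces hand-ranked results and rank invariance", {
  kw <- kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(kw$H, 27 / 7, tolerance = 1e-12)
  expect_equal(kw$df, 1L)

  same <- kruskal_wallis(list(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(same$H, 0)
  expect_equal(same$p, 1)

  set.seed(8)
  g <- list(rnorm(20), rnorm(15, 1), rnorm(10))
  expect_equal(kruskal_wallis(g)$H,
               kruskal_wallis(lapply(g, function(x) exp(x)))$H,
               tolerance = 1e-12)
  expect_error(kruskal_wallis(list(1:3)), "two groups")
  expect_error(kruskal_wallis(list(1:3, numeric())), "at least one")
})

test_that("Kruskal-Wallis agrees with the stats reference to 1e-10 (with ties)", {
  set.seed(99)
  for (i in 1:40) {
    k <- sample(2:4, 1)
    g <- lapply(seq_len(k), function(j) {
      sample(1:8, sample(3:12, 1), replace = TRUE)  # heavy ties
    })
    ours <- kruskal_wallis(g)
    ref <- kruskal.test(unlist(g), factor(rep(seq_len(k), lengths(g))))
    expect_equal(ours$H, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(ours$p, ref$p.value, tolerance = 1e-10)
  }
})

test_that("age comparison recovers a bimodal mixture and flags missing birth dates", {
  sim <- simulate_dataset(make_example_scenario("effusion_rr",
                                                n_patients = 1500, seed = 17))
  eff <- evaluate_cohort(sim$dataset, parse_cohort_definition(
    example_definition_json("pleural_effusion")))
  oth <- evaluate_cohort(sim$dataset, parse_cohort_definition(
    example_definition_json("others")))
  cmp <- age_at_entry_comparison(sim$dataset, list(eff, oth))
  expect_lt(cmp$summaries$median[cmp$summaries$cohort == "Pleural Effusion"],
            cmp$summaries$median[cmp$summaries$cohort == "Others"])
  d <- cmp$density[cmp$density$cohort == "Others", ]
  modes <- density_modes(d$age, d$density)
  expect_true(any(abs(modes - 1) < 0.5))
  expect_true(any(abs(modes - 15) < 0.5))
  expect_lt(cmp$kw$p, 0.05)

  # degenerate cohort: all ages equal
  ds <- tiny_dataset()
  one <- make_cohort(c("P1", "P3"),
                     ds$patients$date_of_birth[match(c("P1", "P3"), ds$patients$patient_id)] +
                       round(1.0 * 365.25), "unit")
  two <- make_cohort(c("P2", "P5"),
                     ds$patients$date_of_birth[match(c("P2", "P5"), ds$patients$patient_id)] +
                       round(5.0 * 365.25), "five")
  cmp2 <- age_at_entry_comparison(ds, list(one, two))
  expect_equal(cmp2$summaries$median[1], 1.0, tolerance = 1e-2)

  ds$patients$date_of_birth[ds$patients$patient_id == "P1"] <- NA
  expect_warning(cmp3 <- age_at_entry_comparison(ds, list(one, two)), "dropped")
  expect_equal(cmp3$summaries$n_dropped[1], 1)
})

test_that("two cohorts from one age law give a null-uniform KW p-value", {
  set.seed(123)
  ps <- vapply(1:200, function(i) {
    kruskal_wallis(list(rlnorm(60, 1, 0.5), rlnorm(60, 1, 0.5)))$p
  }, numeric(1))
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})
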