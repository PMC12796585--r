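test_that("constant logistic data fit a constant location curve", {
  t <- seq(0, 100, length.out = 60)
  y <- rep(37, 60)
  m <- suppressWarnings(
    fit_reference_model(t, y, "logistic", smooth_spec(n_basis = 8, lambda = 1))
  )
  mu <- predict_params(m, seq(1, 99, by = 7))$mu
  expect_lt(max(abs(mu - 37)), 1e-6)
})

test_that("SHASH parameter recovery on a linear trend (generator truth)", {
  set.seed(500)
  n <- 500
  t <- runif(n, 0, 3)
  y <- rshash(n, 50 + 10 * t, 5, 0.5, 1)
  m <- fit_reference_model(t, y, "shash", smooth_spec(lambda = 10))
  grid <- seq(0.1, 2.9, length.out = 50)
  med_true <- 50 + 10 * grid + 5 * sinh(0.5)  # SHASH median = mu + sigma*sinh(nu/tau)
  med_fit <- predict_centiles(m, grid, 0.5)$value
  expect_lte(sqrt(mean((med_fit - med_true)^2)), 1.0)
  expect_lt(abs(m$nu - 0.5), 0.25)
  expect_true(m$diagnostics$converged)
})

test_that("the fit is deterministic and invariant to observation order", {
  set.seed(9)
  t <- runif(120, 0, 10)
  y <- rshash(120, 5 + 0.2 * t, 1, 0.3, 1)
  sm <- smooth_spec(n_basis = 10, lambda = 5)
  m1 <- fit_reference_model(t, y, "shash", sm)
  perm <- sample(120)
  m2 <- fit_reference_model(t[perm], y[perm], "shash", sm)
  expect_identical(m1$beta_mu, m2$beta_mu)
  expect_identical(m1$nu, m2$nu)
})

test_that("small samples trigger the fallback/refusal paths", {
  set.seed(2)
  # fewer observations than spline coefficients: refused
  expect_error(fit_reference_model(runif(10), rnorm(10), "shash"),
               "fewer observations")
  # 50 > n >= basis: SHASH falls back to the normal limit with fixed shape
  t <- runif(40, 0, 1); y <- rnorm(40)
  expect_warning(
    m <- fit_reference_model(t, y, "shash", smooth_spec(n_basis = 6, lambda = 10)),
    "normal limit"
  )
  expect_equal(m$nu, 0)
  expect_equal(m$tau, 1)
  expect_true(m$shape_fixed)
})

test_that("centile curves do not cross and calibrate on training data", {
  set.seed(31)
  n <- 500
  t <- runif(n, 0, 5)
  y <- rshash(n, 30 - 2 * t, 3, -0.4, 1.1)
  m <- fit_reference_model(t, y, "shash", smooth_spec(lambda = 10))
  grid <- seq(0.2, 4.8, length.out = 40)
  cc <- predict_centiles(m, grid, c(0.25, 0.5, 0.75))
  wide <- tidyr::pivot_wider(cc, id_cols = "time", names_from = "centile",
                             values_from = "value")
  expect_true(all(wide$`0.25` < wide$`0.5` & wide$`0.5` < wide$`0.75`))
  below75 <- mean(y < predict_centiles(m, t, 0.75)$value)
  expect_lt(abs(below75 - 0.75), 0.04)
  # symmetric family: median curve equals the location curve
  set.seed(32)
  y0 <- rshash(200, 10, 2, 0, 1)
  t0 <- runif(200, 0, 1)
  m0 <- fit_reference_model(t0, y0, "shash", smooth_spec(n_basis = 6, lambda = 100))
  p0 <- predict_params(m0, c(0.3, 0.7))
  med0 <- predict_centiles(m0, c(0.3, 0.7), 0.5)$value
  expect_equal(med0, p0$mu + p0$sigma * sinh(m0$nu / m0$tau), tolerance = 1e-8)
})

test_that("z-scores are the probit of the model centile, flagged outside the domain", {
  set.seed(77)
  t <- runif(200, 0, 10)
  y <- rshash(200, 100, 10, 0.2, 1)
  m <- fit_reference_model(t, y, "shash", smooth_spec(n_basis = 8, lambda = 100))
  med <- predict_centiles(m, 5, 0.5)$value
  zs <- zscore(m, 5, med)
  expect_equal(zs$z, 0, tolerance = 1e-8)
  expect_equal(zs$centile, 0.5, tolerance = 1e-8)
  q75 <- predict_centiles(m, 5, 0.75)$value
  zs75 <- zscore(m, 5, q75)
  expect_equal(zs75$centile, 0.75, tolerance = 1e-8)
  expect_equal(zs75$z, qnorm(0.75), tolerance = 1e-6)
  out <- zscore(m, 99, 100)
  expect_true(out$extrapolated)
  expect_true(is.finite(out$z))
})

test_that("fitted models survive a JSON round trip", {
  set.seed(5)
  t <- runif(150, 0, 2); y <- rshash(150, 20 + t, 2, 0.3, 1)
  m <- fit_reference_model(t, y, "shash", smooth_spec(n_basis = 8, lambda = 10))
  f <- withr::local_tempfile(fileext = ".json")
  save_reference_model(m, f)
  m2 <- load_reference_model(f)
  grid <- seq(0.1, 1.9, length.out = 11)
  expect_equal(predict_centiles(m2, grid, 0.5)$value,
               predict_centiles(m, grid, 0.5)$value, tolerance = 1e-12)
  expect_equal(m2$nu, m$nu)
})

test_that("a consult scores a known-centile patient sensibly end to end", {
  cfg <- make_example_scenario("transplant_consult", n_patients = 40, seed = 60)
  sim <- simulate_dataset(cfg)
  def <- parse_cohort_definition(example_definition_json("transplant_success"))
  co <- evaluate_cohort(sim$dataset, def)
  pat <- co[1, ]; cmp <- co[-1, ]
  attr(pat, "cohort_name") <- "Patient of Interest"
  attr(cmp, "cohort_name") <- "Transplant Success"
  rep <- consult(sim$dataset, pat, cmp, "CREAT",
                 smooth = smooth_spec(n_basis = 10, lambda = 10))
  expect_s3_class(rep, "consult_report")
  expect_true(all(is.finite(rep$scores$z)))
  expect_true(all(rep$scores$time >= 7 & rep$scores$time <= 730))
  expect_identical(rep$comparator_model$family, "shash")
  f <- withr::local_tempfile(fileext = ".json")
  write_consult_report(rep, f)
  expect_true(jsonlite::validate(paste(readLines(f), collapse = "\n")))

  # errors: multi-patient "patient", and no in-window observations
  expect_error(consult(sim$dataset, cmp, cmp, "CREAT"), "exactly one")
  expect_error(consult(sim$dataset, pat, cmp, "NOCODE"), "no \"NOCODE\" observations")
})
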