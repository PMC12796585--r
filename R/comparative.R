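# Two-cohort comparison: relative-risk scans over comorbidity codes, the
# Kruskal-Wallis rank-sum test, and age-at-entry distribution comparison.

#' Relative risk from a 2x2 table with Katz log confidence interval
#'
#' `rr = (a/n1) / (b/n2)`; the CI is the Katz log-normal interval
#' `exp(log(rr) +/- z * sqrt(1/a - 1/n1 + 1/b - 1/n2))`. When either event
#' count is zero, 0.5 is added to both `a` and `b` and 1 to both totals for
#' estimation, and the result is flagged `corrected`.
#'
#' @param a events in the exposed cohort (patient-level count).
#' @param n1 exposed cohort size (`> 0`).
#' @param b events in the comparator cohort.
#' @param n2 comparator cohort size (`> 0`).
#' @param alpha significance level (default 0.05 for a 95% interval).
#' @return an object of class `rr_estimate`: list with `a`, `n1`, `b`, `n2`,
#'   `rr`, `ci_low`, `ci_high`, `alpha`, `corrected`.
#' @examples
#' relative_risk(4, 10, 2, 20) # rr = 4, CI ~ (0.88, 18.3)
#' @export
relative_risk <- function(a, n1, b, n2, alpha = 0.05) {
  if (n1 <= 0 || n2 <= 0) abort("`n1` and `n2` must be positive")
  if (a > n1 || b > n2 || a < 0 || b < 0) abort("event counts must lie in [0, cohort size]")
  corrected <- (a == 0 || b == 0)
  if (corrected) {
    ae <- a + 0.5; be <- b + 0.5; n1e <- n1 + 1; n2e <- n2 + 1
  } else {
    ae <- a; be <- b; n1e <- n1; n2e <- n2
  }
  rr <- (ae / n1e) / (be / n2e)
  se <- sqrt(1 / ae - 1 / n1e + 1 / be - 1 / n2e)
  z <- qnorm(1 - alpha / 2)
  structure(list(a = a, n1 = n1, b = b, n2 = n2, rr = rr,
                 ci_low = exp(log(rr) - z * se), ci_high = exp(log(rr) + z * se),
                 alpha = alpha, corrected = corrected),
            class = "rr_estimate")
}

#' @export
print.rr_estimate <- function(x, ...) {
  cat(sprintf("RR = %.3g (%.0f%% CI %.3g-%.3g)%s  [%d/%d vs %d/%d]\n",
              x$rr, 100 * (1 - x$alpha), x$ci_low, x$ci_high,
              if (x$corrected) " [zero-cell corrected]" else "",
              x$a, x$n1, x$b, x$n2))
  invisible(x)
}

patients_with_code_category <- function(dataset, cohort, domain, code_level) {
  ev <- semi_join(dataset$events[[domain]], as_tibble(cohort), by = "patient_id")
  ev$category <- substr(ev$code, 1L, code_level)
  distinct(ev, patient_id, category)
}

#' Relative-risk scan over comorbidity categories
#'
#' For every code category (default: 3-character ICD-10 level) observed in
#' either cohort, computes the relative risk of having at least one such
#' event (patient-level) in the exposed cohort versus the comparator.
#' Categories matching `exclude_prefixes` — typically the cohort-defining
#' code itself — are dropped. Sorted by `rr` descending; ties broken by
#' narrower CI, then alphabetically.
#'
#' @param dataset an `ehr_dataset`.
#' @param exposed,comparator disjoint `cohort`s.
#' @param domain event domain to scan (default `"diagnosis"`).
#' @param exclude_prefixes code prefixes to drop from the scan.
#' @param top_k rows to keep (default 10).
#' @param alpha CI significance level.
#' @param code_level characters of the code defining a category (default 3).
#' @return tibble of class `rr_scan` with columns `code`, `a`, `n1`, `b`,
#'   `n2`, `rr`, `ci_low`, `ci_high`, `corrected`.
#' @export
relative_risk_scan <- function(dataset, exposed, comparator,
                               domain = "diagnosis",
                               exclude_prefixes = character(),
                               top_k = 10, alpha = 0.05, code_level = 3L) {
  overlap <- intersect(exposed$patient_id, comparator$patient_id)
  if (length(overlap)) {
    abort(paste0("exposed and comparator cohorts overlap (",
                 length(overlap), " shared patient(s)); the comparison is ill-posed"))
  }
  n1 <- nrow(exposed); n2 <- nrow(comparator)
  if (n1 == 0L || n2 == 0L) abort("both cohorts must be non-empty")
  exclude_prefixes <- normalize_code(exclude_prefixes)

  exp_cat <- patients_with_code_category(dataset, exposed, domain, code_level)
  cmp_cat <- patients_with_code_category(dataset, comparator, domain, code_level)
  cats <- sort(union(unique(exp_cat$category), unique(cmp_cat$category)))
  if (length(exclude_prefixes)) cats <- cats[!code_matches(cats, exclude_prefixes)]

  rows <- lapply(cats, function(cat) {
    a <- sum(exp_cat$category == cat)
    b <- sum(cmp_cat$category == cat)
    est <- relative_risk(a, n1, b, n2, alpha)
    tibble(code = cat, a = a, n1 = n1, b = b, n2 = n2, rr = est$rr,
           ci_low = est$ci_low, ci_high = est$ci_high,
           corrected = est$corrected)
  })
  out <- bind_rows(rows) %>%
    mutate(ci_width = ci_high - ci_low) %>%
    arrange(dplyr::desc(rr), ci_width, code) %>%
    select(-ci_width) %>%
    head(top_k)
  structure(out, class = c("rr_scan", class(out)), alpha = alpha)
}

#' Kruskal-Wallis rank-sum test
#'
#' Rank-based k-sample test of distributional location using mid-ranks for
#' ties:
#' `H = (12 / (N (N+1)) * sum n_i (Rbar_i - (N+1)/2)^2) / (1 - sum(t^3 - t) / (N^3 - N))`,
#' with the p-value from the upper tail of the chi-square distribution on
#' `k - 1` degrees of freedom. Invariant under any strictly increasing
#' transformation of the values.
#'
#' @param groups list of numeric vectors, each non-empty, at least two.
#' @return an object of class `kw_result`: list with `H`, `df`, `p`.
#' @examples
#' kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6))) # H = 27/7
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) abort("need at least two groups")
  if (any(vapply(groups, length, integer(1)) == 0L)) {
    abort("every group must contain at least one observation")
  }
  x <- unlist(groups, use.names = FALSE)
  if (anyNA(x)) abort("values must not be missing")
  g <- rep(seq_along(groups), vapply(groups, length, integer(1)))
  N <- length(x)
  r <- rank(x)  # mid-ranks for ties
  rbar <- tapply(r, g, mean)
  ni <- tabulate(g)
  num <- 12 / (N * (N + 1)) * sum(ni * (rbar - (N + 1) / 2)^2)
  ties <- table(x)
  denom <- 1 - sum(ties^3 - ties) / (N^3 - N)
  H <- if (denom <= 0) 0 else num / denom  # all values identical
  df <- length(groups) - 1L
  structure(list(H = H, df = df, p = pchisq(H, df, lower.tail = FALSE)),
            class = "kw_result")
}

#' @export
print.kw_result <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis: H = %.4f, df = %d, p = %.4g\n", x$H, x$df, x$p))
  invisible(x)
}

#' Compare age at cohort entry across cohorts
#'
#' Computes each member's age at their index date, summarises per cohort
#' (n, median, quartiles), evaluates kernel-density curves on a shared grid
#' (Gaussian kernel, normal-reference bandwidth), and tests for a location
#' difference with [kruskal_wallis()]. Members without a recorded date of
#' birth are dropped with a warning and counted in the summary.
#'
#' @param dataset an `ehr_dataset`.
#' @param cohorts list of two or more `cohort`s.
#' @param bw bandwidth rule or value passed to [stats::density()]
#'   (default `"nrd0"`, the normal reference rule).
#' @param grid_n points in the shared density grid.
#' @return object of class `age_comparison`: list with `summaries` (tibble:
#'   cohort, n, n_dropped, median, q25, q75), `density` (tibble: cohort,
#'   age, density on a shared grid), `ages` (per-cohort list), and `kw`.
#' @export
age_at_entry_comparison <- function(dataset, cohorts, bw = "nrd0", grid_n = 512) {
  if (inherits(cohorts, "cohort")) abort("supply a list of at least two cohorts")
  stopifnot(length(cohorts) >= 2L)
  ages <- lapply(cohorts, function(co) {
    mem <- left_join(as_tibble(co), dataset$patients, by = "patient_id")
    miss <- is.na(mem$date_of_birth)
    if (any(miss)) {
      warn(sprintf("cohort \"%s\": dropped %d member(s) without date_of_birth",
                   cohort_name(co), sum(miss)))
    }
    list(age = age_years(mem$date_of_birth[!miss], mem$index_date[!miss]),
         dropped = sum(miss))
  })
  names(ages) <- vapply(cohorts, cohort_name, character(1))

  summaries <- bind_rows(lapply(names(ages), function(nm) {
    a <- ages[[nm]]$age
    tibble(cohort = nm, n = length(a), n_dropped = ages[[nm]]$dropped,
           median = median(a), q25 = quantile(a, 0.25, names = FALSE),
           q75 = quantile(a, 0.75, names = FALSE))
  }))

  all_ages <- unlist(lapply(ages, `[[`, "age"))
  rng <- range(all_ages)
  pad <- 0.05 * diff(rng)
  grid <- seq(max(0, rng[1] - pad), rng[2] + pad, length.out = grid_n)
  dens <- bind_rows(lapply(names(ages), function(nm) {
    a <- ages[[nm]]$age
    if (length(a) < 2L) {
      # a density needs >= 2 points; degenerate cohorts get a flat zero curve
      return(tibble(cohort = nm, age = grid, density = 0))
    }
    d <- density(a, bw = bw, from = grid[1], to = grid[grid_n], n = grid_n)
    tibble(cohort = nm, age = d$x, density = d$y)
  }))

  structure(list(summaries = summaries, density = dens,
                 ages = lapply(ages, `[[`, "age"),
                 kw = kruskal_wallis(lapply(ages, `[[`, "age"))),
            class = "age_comparison")
}

#' @export
print.age_comparison <- function(x, ...) {
  cat("<age_comparison>\n")
  print(x$summaries)
  print(x$kw)
  invisible(x)
}

#' Local maxima of a density curve
#'
#' Utility for inspecting multimodality of an [age_at_entry_comparison()]
#' density: returns grid locations that are strict local maxima above a
#' height floor (a fraction of the global peak, filtering grid noise).
#'
#' @param age,dens numeric vectors, the density grid and heights.
#' @param min_height_frac floor as a fraction of `max(dens)` (default 0.05).
#' @return numeric vector of mode locations.
#' @export
density_modes <- function(age, dens, min_height_frac = 0.05) {
  n <- length(dens)
  is_max <- c(FALSE, dens[2:(n - 1)] > dens[1:(n - 2)] &
                dens[2:(n - 1)] > dens[3:n], FALSE)
  age[is_max & dens >= min_height_frac * max(dens)]
}
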