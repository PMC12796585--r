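# Synthetic EHR generator. Emits datasets in the common data model with the
# statistical structure the analytics modules assume — latent patient groups,
# per-group coded-event prevalences, waiting-time distributions for follow-up
# events, and longitudinal observations drawn from a time-varying sinh-arcsinh
# law sampled at Poisson-process visit times — together with the ground truth
# needed for recovery tests.

#' Parameter curves over time since index
#'
#' Small vocabulary of deterministic functions of time (days since cohort
#' entry) used for distribution parameters in trajectory specifications:
#' constant, linear (`a + b*t`), and exponential decay towards a base level
#' (`base + amplitude * exp(-t / timescale)`), the natural shape for a
#' marker that settles after an index procedure.
#'
#' @param value,intercept,slope,base,amplitude,timescale curve parameters;
#'   `timescale` is in days and must be positive.
#' @return an object of class `param_curve`.
#' @export
curve_constant <- function(value) {
  structure(list(type = "constant", value = value), class = "param_curve")
}

#' @rdname curve_constant
#' @export
curve_linear <- function(intercept, slope) {
  structure(list(type = "linear", intercept = intercept, slope = slope),
            class = "param_curve")
}

#' @rdname curve_constant
#' @export
curve_exp_decay <- function(base, amplitude, timescale) {
  stopifnot(timescale > 0)
  structure(list(type = "exp_decay", base = base, amplitude = amplitude,
                 timescale = timescale), class = "param_curve")
}

#' Evaluate a parameter curve
#' @param curve a `param_curve`.
#' @param t numeric vector of days since index.
#' @return numeric vector of curve values.
#' @export
eval_curve <- function(curve, t) {
  switch(curve$type,
    constant = rep(curve$value, length(t)),
    linear = curve$intercept + curve$slope * t,
    exp_decay = curve$base + curve$amplitude * exp(-t / curve$timescale),
    abort(paste("unknown curve type:", curve$type))
  )
}

#' Coded-event panel for a simulated group
#'
#' One row per code a group member may acquire. `prevalence` is the
#' probability that a member has at least one such event. If `wait_dist` is
#' `NA` the event date is uniform between the member's index date and the
#' coverage end (the event is always inside the dataset); `"exponential"` or
#' `"weibull"` place the event at index + a waiting-time draw (in days),
#' dropping draws that land beyond the coverage end — i.e. natural
#' administrative right-censoring with a known truth.
#'
#' @param domain,code_system,code,display event fields (vectors recycled to
#'   a common length).
#' @param prevalence per-code probability in `[0, 1]`.
#' @param wait_dist `NA`, `"exponential"` or `"weibull"`.
#' @param wait_scale scale of the waiting-time law in days (the mean, for
#'   the exponential).
#' @param wait_shape Weibull shape (ignored otherwise).
#' @return tibble usable as a group's `panel`.
#' @export
code_panel <- function(domain, code_system, code, display, prevalence,
                       wait_dist = NA_character_, wait_scale = NA_real_,
                       wait_shape = NA_real_) {
  tibble(domain = domain, code_system = code_system,
         code = normalize_code(code), display = display,
         prevalence = prevalence, wait_dist = wait_dist,
         wait_scale = wait_scale, wait_shape = wait_shape)
}

#' Longitudinal observation model for a simulated group
#'
#' Members receive observation events at visit times drawn from a homogeneous
#' Poisson process over `window` (days since index); each value is drawn from
#' `SHASH(mu(t), sigma(t), nu, tau)` at the visit day. If `target_centile` is
#' set, values are placed deterministically on that centile of the generating
#' law instead of being drawn — used to construct patients with a known
#' position relative to the reference population.
#'
#' @param code,display,unit observation concept fields.
#' @param window length-2 numeric, first and last day since index at which
#'   visits occur.
#' @param visit_rate expected visits per day.
#' @param mu,sigma `param_curve`s for location and scale (scale must be
#'   positive over the window).
#' @param nu,tau scalar skewness and tail weight.
#' @param target_centile optional probability; see above.
#' @return an object of class `trajectory_spec`.
#' @export
trajectory_spec <- function(code, display, unit, window, visit_rate,
                            mu, sigma, nu = 0, tau = 1,
                            target_centile = NULL) {
  stopifnot(length(window) == 2L, window[1] <= window[2], visit_rate >= 0,
            inherits(mu, "param_curve"), inherits(sigma, "param_curve"))
  structure(list(code = normalize_code(code), display = display, unit = unit,
                 window = as.numeric(window), visit_rate = visit_rate,
                 mu = mu, sigma = sigma, nu = nu, tau = tau,
                 target_centile = target_centile),
            class = "trajectory_spec")
}

#' Latent group specification
#'
#' @param label group name (recorded in the ground truth, never in the
#'   emitted dataset).
#' @param proportion population share; proportions across groups must sum
#'   to 1.
#' @param age_meanlog,age_sdlog,age_weight parameters of a lognormal mixture
#'   for age at index (years); equal-length vectors, weights summing to 1.
#'   A two-component mixture reproduces the bimodal age-at-surgery pattern
#'   seen in paediatric cardiac cohorts.
#' @param sex_probs named probabilities for `female`, `male`, `other`.
#' @param panel [code_panel()] tibble (may be empty).
#' @param trajectories list of [trajectory_spec()]s.
#' @return an object of class `group_spec`.
#' @export
group_spec <- function(label, proportion,
                       age_meanlog = log(8), age_sdlog = 0.6, age_weight = 1,
                       sex_probs = c(female = 0.48, male = 0.50, other = 0.02),
                       panel = code_panel(character(), character(), character(),
                                          character(), numeric()),
                       trajectories = list()) {
  stopifnot(length(age_meanlog) == length(age_sdlog),
            length(age_meanlog) == length(age_weight))
  structure(list(label = label, proportion = proportion,
                 age_meanlog = age_meanlog, age_sdlog = age_sdlog,
                 age_weight = age_weight / sum(age_weight),
                 sex_probs = sex_probs, panel = panel,
                 trajectories = trajectories),
            class = "group_spec")
}

#' Simulation configuration
#'
#' @param n_patients number of patients to generate.
#' @param seed integer master seed; every patient derives an independent
#'   substream from it, so output is identical across runs and stable under
#'   reordering.
#' @param coverage_window length-2 Date vector of dataset coverage.
#' @param groups list of [group_spec()]s; proportions must sum to 1.
#' @param index_event list with `domain`, `code_system`, `code` (possibly a
#'   vector of alternatives sampled uniformly), `display`; defines each
#'   patient's time zero.
#' @param min_followup_days index dates are drawn so that at least this many
#'   days of coverage remain after entry (default 28).
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_patients, seed, coverage_window, groups,
                       index_event, min_followup_days = 28) {
  cfg <- structure(list(n_patients = n_patients, seed = as.integer(seed),
                        coverage_window = as.Date(coverage_window),
                        groups = groups, index_event = index_event,
                        min_followup_days = min_followup_days),
                   class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(config) {
  fail <- function(field, msg) abort(paste0("invalid simulation config: `", field, "` ", msg))
  if (!is.numeric(config$n_patients) || config$n_patients < 1) {
    fail("n_patients", "must be a positive count")
  }
  if (length(config$coverage_window) != 2L || anyNA(config$coverage_window) ||
      config$coverage_window[1] > config$coverage_window[2]) {
    fail("coverage_window", "must be an ordered pair of dates")
  }
  props <- vapply(config$groups, function(g) g$proportion, numeric(1))
  if (abs(sum(props) - 1) > 1e-9) fail("groups.proportion", "values must sum to 1")
  for (i in seq_along(config$groups)) {
    g <- config$groups[[i]]
    if (nrow(g$panel) && any(g$panel$prevalence < 0 | g$panel$prevalence > 1)) {
      fail(sprintf("groups[%d].panel.prevalence", i), "must lie in [0, 1]")
    }
    for (tr in g$trajectories) {
      grid <- seq(tr$window[1], tr$window[2], length.out = 101)
      if (any(eval_curve(tr$sigma, grid) <= 0)) {
        fail(sprintf("groups[%d].trajectories.sigma", i),
             "must be positive over the whole window")
      }
      if (tr$tau <= 0) fail(sprintf("groups[%d].trajectories.tau", i), "must be positive")
    }
  }
  ie <- config$index_event
  if (is.null(ie$domain) || is.null(ie$code)) {
    fail("index_event", "must give `domain` and `code`")
  }
  invisible(config)
}

sample_mixture_lognormal <- function(meanlog, sdlog, weight) {
  k <- sample.int(length(weight), 1L, prob = weight)
  rlnorm(1, meanlog[k], sdlog[k])
}

#' Simulate a dataset with ground truth
#'
#' Generates one patient at a time from an independent substream of the
#' master seed: group membership, sex, age at index (lognormal mixture),
#' an index event at a uniform date inside the coverage window (leaving
#' `min_followup_days` of follow-up), panel events by per-code Bernoulli
#' prevalence with optional waiting times, and observation trajectories at
#' Poisson visit times. The emitted dataset always passes
#' [validate_dataset()] with zero issues.
#'
#' @param config a [sim_config()].
#' @return list with `dataset` (an `ehr_dataset`) and `truth` (class
#'   `sim_truth`: per-patient latent group and index date, per-code
#'   configured prevalences, waiting-time parameters, trajectory laws, and
#'   the config itself).
#' @export
simulate_dataset <- function(config) {
  validate_sim_config(config)
  start <- config$coverage_window[1]
  end <- config$coverage_window[2]
  n_index_days <- as.numeric(end - start) - config$min_followup_days
  if (n_index_days < 0) {
    abort("invalid simulation config: `coverage_window` shorter than `min_followup_days`")
  }
  props <- vapply(config$groups, function(g) g$proportion, numeric(1))
  cum <- cumsum(props)
  ie <- config$index_event

  pat_rows <- vector("list", config$n_patients)
  ev_rows <- vector("list", config$n_patients)
  truth_rows <- vector("list", config$n_patients)

  for (i in seq_len(config$n_patients)) {
    set.seed(derive_seed(config$seed, i))
    pid <- sprintf("P%06d", i)
    g_idx <- findInterval(runif(1), cum) + 1L
    g <- config$groups[[g_idx]]
    sex <- sample(names(g$sex_probs), 1L, prob = g$sex_probs)
    age <- sample_mixture_lognormal(g$age_meanlog, g$age_sdlog, g$age_weight)
    index_date <- start + floor(runif(1) * (n_index_days + 1))
    dob <- index_date - round(age * 365.25)

    idx_code <- if (length(ie$code) > 1L) sample(ie$code, 1L) else ie$code
    idx_disp <- if (length(ie$display) > 1L) ie$display[match(idx_code, ie$code)] else ie$display
    events <- list(tibble(
      domain = ie$domain, code_system = ie$code_system %||% "OPCS-4",
      code = idx_code, display = idx_disp %||% idx_code,
      event_date = index_date, value = NA_real_, unit = NA_character_
    ))

    if (nrow(g$panel)) {
      for (j in seq_len(nrow(g$panel))) {
        row <- g$panel[j, ]
        if (runif(1) >= row$prevalence) next
        if (is.na(row$wait_dist)) {
          d <- index_date + floor(runif(1) * (as.numeric(end - index_date) + 1))
        } else {
          w <- switch(row$wait_dist,
            exponential = rexp(1, rate = 1 / row$wait_scale),
            weibull = rweibull(1, shape = row$wait_shape, scale = row$wait_scale),
            abort(paste("invalid simulation config: `wait_dist`", row$wait_dist))
          )
          d <- index_date + round(w)
          if (d > end) next  # beyond coverage: censored by design
        }
        events[[length(events) + 1L]] <- tibble(
          domain = row$domain, code_system = row$code_system, code = row$code,
          display = row$display, event_date = d,
          value = NA_real_, unit = NA_character_
        )
      }
    }

    for (tr in g$trajectories) {
      t_max <- min(tr$window[2], as.numeric(end - index_date))
      if (t_max < tr$window[1]) next
      n_vis <- rpois(1, tr$visit_rate * (t_max - tr$window[1]))
      if (n_vis == 0L) next
      t_day <- round(sort(runif(n_vis, tr$window[1], t_max)))
      mu_t <- eval_curve(tr$mu, t_day)
      sg_t <- eval_curve(tr$sigma, t_day)
      val <- if (is.null(tr$target_centile)) {
        rshash(n_vis, mu_t, sg_t, tr$nu, tr$tau)
      } else {
        qshash(rep(tr$target_centile, n_vis), mu_t, sg_t, tr$nu, tr$tau)
      }
      events[[length(events) + 1L]] <- tibble(
        domain = "observation", code_system = "observation_concept",
        code = tr$code, display = tr$display,
        event_date = index_date + t_day, value = val, unit = tr$unit
      )
    }

    pat_rows[[i]] <- tibble(patient_id = pid, date_of_birth = dob, sex = sex)
    ev <- bind_rows(events)
    ev$patient_id <- pid
    ev_rows[[i]] <- ev
    truth_rows[[i]] <- tibble(
      patient_id = pid, group = g$label, index_date = index_date,
      age_at_index = as.numeric(index_date - dob) / 365.25
    )
  }

  ev_all <- bind_rows(ev_rows)
  events <- lapply(EVENT_DOMAINS, function(d) ev_all[ev_all$domain == d, -1])
  names(events) <- EVENT_DOMAINS
  dataset <- ehr_dataset(bind_rows(pat_rows), events, config$coverage_window)

  prevalence <- bind_rows(lapply(config$groups, function(g) {
    if (!nrow(g$panel)) return(NULL)
    mutate(g$panel[, c("domain", "code", "prevalence", "wait_dist",
                       "wait_scale", "wait_shape")], group = g$label)
  }))
  trajectories <- lapply(config$groups, function(g) g$trajectories)
  names(trajectories) <- vapply(config$groups, function(g) g$label, character(1))

  truth <- structure(
    list(patients = bind_rows(truth_rows), prevalence = prevalence,
         trajectories = trajectories, config = config),
    class = "sim_truth"
  )
  list(dataset = dataset, truth = truth)
}
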