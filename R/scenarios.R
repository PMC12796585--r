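# Ready-made simulation scenarios. Each structurally mirrors one of the four
# workloads the platform is designed for: an informatics consult on a
# post-transplant biochemical marker, a medication-frequency summary for a
# dialysis cohort, a two-cohort comorbidity relative-risk scan, and a
# time-to-event question about post-operative echocardiography. Prevalences
# and waiting-time laws are free choices documented in the methods vignette;
# the real source distributions are not public.

#' Ready-made example simulation scenarios
#'
#' @param name one of `"transplant_consult"`, `"dialysis_meds"`,
#'   `"effusion_rr"`, `"echo_tte"`.
#' @param n_patients number of patients; the default per scenario is scaled
#'   so the qualifying cohort is roughly the size reported for the
#'   corresponding real-world analysis.
#' @param seed master seed for [simulate_dataset()].
#' @return a [sim_config()].
#' @export
make_example_scenario <- function(name, n_patients = NULL, seed = 20260101L) {
  valid <- c("transplant_consult", "dialysis_meds", "effusion_rr", "echo_tte")
  if (!is.character(name) || length(name) != 1L || !name %in% valid) {
    abort(paste0("unknown scenario; valid names are: ", paste(valid, collapse = ", ")))
  }
  window <- as.Date(c("2021-07-01", "2023-06-30"))
  switch(name,
    transplant_consult = {
      creat <- function(target = NULL) trajectory_spec(
        code = "CREAT", display = "Serum creatinine", unit = "umol/L",
        window = c(7, 730), visit_rate = 20 / 723,
        mu = curve_exp_decay(45, 150, 14),
        sigma = curve_exp_decay(6, 18, 14),
        nu = 0.8, tau = 1, target_centile = target
      )
      sim_config(
        n_patients = n_patients %||% 60, seed = seed, coverage_window = window,
        groups = list(
          group_spec("success", 0.75,
                     age_meanlog = log(9), age_sdlog = 0.55,
                     trajectories = list(creat())),
          group_spec("failure", 0.25,
                     age_meanlog = log(9), age_sdlog = 0.55,
                     panel = code_panel("procedure", "OPCS-4", "X40",
                                        "Compensation for renal failure", 1,
                                        wait_dist = "exponential",
                                        wait_scale = 180),
                     trajectories = list(creat()))
        ),
        index_event = list(domain = "procedure", code_system = "OPCS-4",
                           code = "M01", display = "Transplantation of kidney"),
        min_followup_days = 180
      )
    },
    dialysis_meds = {
      meds <- code_panel(
        "medication", "generic_name",
        c("HEPARIN", "PARACETAMOL", "SODIUM CHLORIDE", "ALFACALCIDOL",
          "LEVOBUPIVACAINE", "EPOETIN", "AMOXICILLIN", "FUROSEMIDE",
          "IRON SUCROSE", "CALCIUM CARBONATE", "ONDANSETRON", "MORPHINE",
          "CEFUROXIME", "ERGOCALCIFEROL", "CHLORHEXIDINE", "AMLODIPINE"),
        c("heparin", "paracetamol", "sodium chloride", "alfacalcidol",
          "levobupivacaine", "epoetin", "amoxicillin", "furosemide",
          "iron sucrose", "calcium carbonate", "ondansetron", "morphine",
          "cefuroxime", "ergocalciferol", "chlorhexidine", "amlodipine"),
        c(0.96, 0.90, 0.89, 0.84, 0.81, 0.65, 0.60, 0.55,
          0.50, 0.45, 0.40, 0.35, 0.30, 0.29, 0.28, 0.25)
      )
      classes <- code_panel(
        "medication", "therapeutic_class",
        c("TC01", "TC02", "TC03", "TC04", "TC05", "TC06", "TC07", "TC08"),
        c("Anticoagulants and protamine", "Fluids and electrolytes",
          "Anaemias and other blood disorders", "Vitamins", "Analgesics",
          "Antibacterials", "Antiemetics", "Antihypertensives"),
        c(0.96, 0.94, 0.93, 0.92, 0.91, 0.70, 0.45, 0.30)
      )
      ckd <- code_panel("diagnosis", "ICD-10", "N18", "Chronic kidney disease", 1)
      sim_config(
        n_patients = n_patients %||% 90, seed = seed, coverage_window = window,
        groups = list(
          group_spec("dialysis_only", 0.8,
                     age_meanlog = log(7), age_sdlog = 0.6,
                     panel = bind_rows(ckd, meds, classes)),
          group_spec("later_transplanted", 0.2,
                     age_meanlog = log(7), age_sdlog = 0.6,
                     panel = bind_rows(
                       ckd, meds, classes,
                       code_panel("procedure", "OPCS-4", "M01",
                                  "Transplantation of kidney", 1,
                                  wait_dist = "exponential", wait_scale = 200)
                     ))
        ),
        index_event = list(domain = "procedure", code_system = "OPCS-4",
                           code = "X40", display = "Compensation for renal failure")
      )
    },
    effusion_rr = {
      comorb <- function(s25, k31, f19, e87) code_panel(
        "diagnosis", "ICD-10",
        c("S25", "K31", "F19", "E87", "R50", "Z38"),
        c("Injury of blood vessels of thorax",
          "Other diseases of stomach and duodenum",
          "Mental and behavioural disorders due to multiple drug use",
          "Other disorders of fluid, electrolyte and acid-base balance",
          "Fever of other and unknown origin", "Liveborn infants"),
        c(s25, k31, f19, e87, 0.40, 0.20)
      )
      effusion_dx <- code_panel("diagnosis", "ICD-10", "J90",
                                "Pleural effusion, not elsewhere classified", 1)
      sim_config(
        n_patients = n_patients %||% 2200, seed = seed, coverage_window = window,
        groups = list(
          group_spec("effusion", 0.32,
                     age_meanlog = c(log(0.98) + 0.45^2, log(15) + 0.25^2),
                     age_sdlog = c(0.45, 0.25), age_weight = c(0.85, 0.15),
                     panel = bind_rows(effusion_dx,
                                       comorb(0.027, 0.027, 0.023, 0.30))),
          group_spec("others", 0.68,
                     age_meanlog = c(log(1) + 0.35^2, log(15) + 0.25^2),
                     age_sdlog = c(0.35, 0.25), age_weight = c(0.5, 0.5),
                     panel = comorb(0.001, 0.001, 0.001, 0.10))
        ),
        index_event = list(
          domain = "procedure", code_system = "OPCS-4",
          code = c("K11", "K25", "K45", "K57"),
          display = c("Repair of defect of interventricular septum",
                      "Plastic repair of mitral valve",
                      "Connection of thoracic artery to coronary artery",
                      "Interventions on heart")
        )
      )
    },
    echo_tte = {
      # Weibull chosen so the waiting-time law has median 3 days and only
      # ~1/375 of draws beyond 14 days: shape k solves (14/3)^k =
      # log(375)/log(2), scale = 3 / log(2)^(1/k).
      k <- log(log(375) / log(2)) / log(14 / 3)
      sc <- 3 / log(2)^(1 / k)
      sim_config(
        n_patients = n_patients %||% 375, seed = seed, coverage_window = window,
        groups = list(
          group_spec("defect_repair", 1,
                     age_meanlog = c(log(0.6) + 0.4^2, log(5) + 0.5^2),
                     age_sdlog = c(0.4, 0.5), age_weight = c(0.6, 0.4),
                     panel = code_panel("procedure", "OPCS-4", "U20",
                                        "Transthoracic echocardiography", 1,
                                        wait_dist = "weibull",
                                        wait_scale = sc, wait_shape = k))
        ),
        index_event = list(domain = "procedure", code_system = "OPCS-4",
                           code = "K11",
                           display = "Repair of defect of interventricular septum")
      )
    }
  )
}

# --- YAML round trip ---------------------------------------------------------

curve_to_list <- function(x) unclass(x)
curve_from_list <- function(x) structure(x, class = "param_curve")

#' Write / read a simulation configuration as YAML
#'
#' @param config a [sim_config()].
#' @param path YAML file path.
#' @return `write_sim_config` returns `path` invisibly; `read_sim_config`
#'   returns a validated [sim_config()].
#' @export
write_sim_config <- function(config, path) {
  lst <- list(
    n_patients = config$n_patients, seed = config$seed,
    coverage_window = format(config$coverage_window, "%Y-%m-%d"),
    min_followup_days = config$min_followup_days,
    index_event = config$index_event,
    groups = lapply(config$groups, function(g) {
      list(label = g$label, proportion = g$proportion,
           age_meanlog = g$age_meanlog, age_sdlog = g$age_sdlog,
           age_weight = g$age_weight, sex_probs = as.list(g$sex_probs),
           panel = lapply(seq_len(nrow(g$panel)), function(j) as.list(g$panel[j, ])),
           trajectories = lapply(g$trajectories, function(tr) {
             out <- unclass(tr)
             out$mu <- curve_to_list(tr$mu)
             out$sigma <- curve_to_list(tr$sigma)
             out
           }))
    })
  )
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  lst <- yaml::read_yaml(path)
  groups <- lapply(lst$groups, function(g) {
    panel <- if (length(g$panel)) {
      bind_rows(lapply(g$panel, function(row) {
        as_tibble(lapply(row, function(v) if (is.null(v)) NA else v))
      }))
    } else {
      code_panel(character(), character(), character(), character(), numeric())
    }
    trajectories <- lapply(g$trajectories, function(tr) {
      trajectory_spec(tr$code, tr$display, tr$unit, unlist(tr$window),
                      tr$visit_rate, curve_from_list(tr$mu),
                      curve_from_list(tr$sigma), tr$nu, tr$tau,
                      tr$target_centile)
    })
    group_spec(g$label, g$proportion, unlist(g$age_meanlog),
               unlist(g$age_sdlog), unlist(g$age_weight),
               unlist(g$sex_probs), panel, trajectories)
  })
  sim_config(lst$n_patients, lst$seed, as.Date(unlist(lst$coverage_window)),
             groups, lst$index_event, lst$min_followup_days)
}
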