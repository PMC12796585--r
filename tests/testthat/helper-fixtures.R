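# Shared fixtures and independent oracles, all built in code.

WIN <- as.Date(c("2021-07-01", "2023-06-30"))

# Five hand-built patients exercising the four example phenotypes:
#   P1 kidney transplant only; P2 transplant then dialysis (failure);
#   P3 dialysis with CKD; P4 cardiac repair with pleural effusion;
#   P5 cardiac procedure without effusion.
tiny_dataset <- function() {
  patients <- tibble::tibble(
    patient_id = paste0("P", 1:5),
    date_of_birth = as.Date(c("2010-01-01", "2005-06-15", "2012-03-01",
                              "2021-01-10", "2006-09-30")),
    sex = c("female", "male", "female", "male", "female")
  )
  procedures <- tibble::tibble(
    patient_id = c("P1", "P2", "P2", "P3", "P4", "P5"),
    code_system = "OPCS-4",
    code = c("M01", "M01", "X40", "X40", "K11", "K25"),
    display = c("Transplantation of kidney", "Transplantation of kidney",
                "Compensation for renal failure", "Compensation for renal failure",
                "Repair of defect of interventricular septum",
                "Plastic repair of mitral valve"),
    event_date = as.Date(c("2022-01-01", "2022-01-01", "2022-06-01",
                           "2022-02-01", "2022-03-01", "2022-04-01"))
  )
  diagnoses <- tibble::tibble(
    patient_id = c("P2", "P3", "P4"),
    code_system = "ICD-10",
    code = c("N18", "N18", "J90"),
    display = c("Chronic kidney disease", "Chronic kidney disease",
                "Pleural effusion, not elsewhere classified"),
    event_date = as.Date(c("2022-05-01", "2022-01-15", "2022-03-10"))
  )
  ehr_dataset(patients, list(procedure = procedures, diagnosis = diagnoses), WIN)
}

# Random small dataset over a fixed code pool (independent of the generator
# module, for cohort-engine oracle testing).
CODE_POOL <- list(
  procedure = c("M01", "M012", "X40", "K11", "K111", "K25", "K45", "U20"),
  diagnosis = c("N18", "J90", "S25", "K31", "F19", "E87", "R50")
)

random_dataset <- function(n_patients, seed) {
  set.seed(seed)
  ids <- sprintf("R%04d", seq_len(n_patients))
  patients <- tibble::tibble(
    patient_id = ids,
    date_of_birth = WIN[1] - sample(365:7300, n_patients, replace = TRUE),
    sex = sample(c("female", "male"), n_patients, replace = TRUE)
  )
  mk <- function(domain) {
    n_ev <- rpois(n_patients, 4)
    tibble::tibble(
      patient_id = rep(ids, n_ev),
      code_system = if (domain == "procedure") "OPCS-4" else "ICD-10",
      code = sample(CODE_POOL[[domain]], sum(n_ev), replace = TRUE),
      display = "x",
      event_date = WIN[1] + sample.int(as.numeric(WIN[2] - WIN[1]) + 1,
                                       sum(n_ev), replace = TRUE) - 1
    )
  }
  ehr_dataset(patients, list(procedure = mk("procedure"),
                             diagnosis = mk("diagnosis")), WIN)
}

random_definition <- function(seed) {
  set.seed(seed)
  pick <- function(domain) {
    criterion(domain, sample(CODE_POOL[[domain]], 1),
              mode = sample(c("include", "exclude"), 1, prob = c(0.4, 0.6)),
              temporal = sample(c("ever", "on_or_after_index", "before_index"), 1))
  }
  idx_dom <- sample(c("procedure", "diagnosis"), 1)
  crits <- list(criterion(idx_dom, sample(CODE_POOL[[idx_dom]],
                                          sample(1:2, 1)),
                          role = "index_candidate"))
  for (k in seq_len(sample(0:2, 1))) {
    crits <- c(crits, list(pick(sample(c("procedure", "diagnosis"), 1))))
  }
  cohort_definition(paste0("rand", seed), crits)
}

# Independent brute-force cohort filter: explicit per-patient loop, no shared
# code with evaluate_cohort.
brute_force_cohort <- function(dataset, definition) {
  pts <- dataset$patients$patient_id
  members <- character()
  index_dates <- as.Date(character())
  prefix_hit <- function(codes, prefixes) {
    hit <- rep(FALSE, length(codes))
    for (p in prefixes) hit <- hit | substr(codes, 1, nchar(p)) == p
    hit
  }
  for (pid in pts) {
    crit_dates <- lapply(definition$criteria, function(cr) {
      ev <- dataset$events[[cr$domain]]
      ev <- ev[ev$patient_id == pid, ]
      if (!is.null(cr$code_system)) ev <- ev[ev$code_system %in% cr$code_system, ]
      ev$event_date[prefix_hit(ev$code, cr$code_prefix)]
    })
    is_idx <- vapply(definition$criteria, function(cr) cr$role == "index_candidate",
                     logical(1))
    idx_dates <- do.call(c, crit_dates[is_idx])
    if (length(idx_dates) == 0L) next
    idx <- min(idx_dates)
    ok <- TRUE
    for (j in seq_along(definition$criteria)) {
      cr <- definition$criteria[[j]]
      if (cr$role == "index_candidate" && cr$temporal == "ever") next
      d <- crit_dates[[j]]
      d <- switch(cr$temporal,
                  ever = d,
                  on_or_after_index = d[d >= idx],
                  before_index = d[d < idx])
      hit <- length(d) > 0L
      if (cr$mode == "include" && !hit) ok <- FALSE
      if (cr$mode == "exclude" && hit) ok <- FALSE
    }
    if (ok) {
      members <- c(members, pid)
      index_dates <- c(index_dates, idx)
    }
  }
  o <- order(members)
  tibble::tibble(patient_id = members[o], index_date = index_dates[o])
}

# JSON documents for the four example phenotype definitions.
example_definition_json <- function(which) {
  switch(which,
    transplant_success = '{
      "name": "Transplant Success",
      "criteria": [
        {"domain": "procedure", "code_prefix": "M01", "role": "index_candidate"},
        {"domain": "procedure", "code_prefix": "X40", "mode": "exclude",
         "temporal": "on_or_after_index"}
      ]}',
    dialysis = '{
      "name": "Dialysis Patients",
      "criteria": [
        {"domain": "procedure", "code_prefix": "X40", "role": "index_candidate"},
        {"domain": "diagnosis", "code_prefix": "N18"},
        {"domain": "procedure", "code_prefix": "M01", "mode": "exclude"}
      ]}',
    pleural_effusion = '{
      "name": "Pleural Effusion",
      "criteria": [
        {"domain": "procedure", "code_prefix": "K", "role": "index_candidate"},
        {"domain": "diagnosis", "code_prefix": "J90"}
      ]}',
    others = '{
      "name": "Others",
      "criteria": [
        {"domain": "procedure", "code_prefix": "K", "role": "index_candidate"},
        {"domain": "diagnosis", "code_prefix": "J90", "mode": "exclude"}
      ]}',
    defect_repair = '{
      "name": "Defect Repair",
      "criteria": [
        {"domain": "procedure", "code_prefix": "K11", "role": "index_candidate"}
      ]}'
  )
}

make_cohort <- function(ids, dates, name = "test") {
  ehrconsult:::new_cohort(
    tibble::tibble(patient_id = ids, index_date = as.Date(dates)), name
  )
}
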