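# Run expr with a private RNG stream, restoring the caller's .Random.seed.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Deterministic per-patient sub-stream so patient i's draws do not depend on
# how many patients precede it.
patient_seed <- function(seed, i) {
  as.integer((as.double(seed) * 48271 + i * 1117) %% 2147483629)
}

#' Configuration for the synthetic OMOP CDM generators
#'
#' Bundles every knob of the four generators ([generate_inpatient_cohort()],
#' [generate_outpatient_visits()], [generate_er_visits()],
#' [generate_patient_journeys()]) with defaults that emulate a single-surgery
#' inpatient study: 300 patients, a planted clinical pathway of 20 day-specific
#' orders applied with probability 0.85-1.0 on days -1..+2 around the
#' operation, 200 day-independent noise orders at probability 0.01-0.15, and a
#' 4-8 day length-of-stay mix. Outpatient, emergency-room and patient-journey
#' sections carry their own sample-size and distribution settings.
#'
#' @param seed Integer seed; every random draw in the generators derives from
#'   it (per-patient sub-streams keep patient-level draws stable under
#'   changes of `n_patients`).
#' @param n_patients Number of patients (inpatient/outpatient/ER: one index
#'   visit per patient; journeys: one multi-visit sequence per patient).
#' @param study_period Length-2 `Date` vector, half-open `[start, end)`.
#' @param surgery_concept_id Procedure concept anchoring the inpatient cohort.
#' @param n_planted,n_noise Number of planted pathway entries / noise orders
#'   generated when `planted_cp` / `noise_orders` are not supplied.
#' @param planted_cp Tibble `(relative_day, concept_id, source_table,
#'   occurrence_probability)`; `NULL` generates one from the seed.
#' @param noise_orders Tibble `(concept_id, source_table, probability)` of
#'   per-day Bernoulli noise orders; `NULL` generates one.
#' @param los_distribution Tibble `(days, prob)` for inpatient length of stay.
#' @param outpatient List: `visits_lambda` (Poisson mean of extra visits per
#'   patient), `event_means` (named per-table Poisson means over the six
#'   outpatient source tables), `date_only_fraction` (named per-table fraction
#'   of rows recorded with a calendar date only).
#' @param er List: `source_distribution` / `discharge_distribution` (named
#'   probabilities over admission-source concept ids), `mean_los_hours`,
#'   `sd_los_hours` (gamma-distributed stay), `event_means` (named per-table
#'   Poisson means).
#' @param journey List: `initial` (named distribution over visit types),
#'   `transition` (row-stochastic matrix over
#'   Outpatient/Inpatient/ER/Checkup/End), `cap` (max visits per patient).
#' @return A validated `synthetic_config` list.
#' @export
#' @examples
#' cfg <- synthetic_config(seed = 1, n_patients = 20)
#' cfg$n_patients
synthetic_config <- function(seed = 1L,
                             n_patients = 300L,
                             study_period = as.Date(c("2018-01-01", "2022-01-01")),
                             surgery_concept_id = 4300001L,
                             n_planted = 20L,
                             n_noise = 200L,
                             planted_cp = NULL,
                             noise_orders = NULL,
                             los_distribution = tibble(
                               days = 4:8, prob = c(0.15, 0.30, 0.25, 0.20, 0.10)),
                             outpatient = list(),
                             er = list(),
                             journey = list()) {
  seed <- as.integer(seed)
  if (is.null(planted_cp)) {
    planted_cp <- with_seed(patient_seed(seed, 0L), default_planted_cp(n_planted))
  }
  if (is.null(noise_orders)) {
    noise_orders <- with_seed(patient_seed(seed, -1L), default_noise_orders(n_noise))
  }
  op_defaults <- list(
    visits_lambda = 2,
    event_means = c(condition_occurrence = 1.2, measurement = 2.0,
                    drug_exposure = 1.5, procedure_occurrence = 1.2,
                    cost = 1.0, observation = 0.5),
    date_only_fraction = c(condition_occurrence = 0.3, drug_exposure = 0.3,
                           cost = 0.3))
  er_defaults <- list(
    source_distribution = c("8536" = 0.70, "44790567" = 0.10, "8716" = 0.05,
                            "8717" = 0.05, "8756" = 0.10),
    discharge_distribution = c("8536" = 0.85, "8717" = 0.10, "44790567" = 0.05),
    mean_los_hours = 5.94, sd_los_hours = 7.6,
    event_means = c(measurement = 3, drug_exposure = 1.5,
                    observation = 1, note = 0.5))
  jn_defaults <- list(
    initial = c(Outpatient = 0.80, Inpatient = 0.05, ER = 0.10,
                Checkup = 0.05, End = 0.00),
    transition = default_journey_transition(),
    cap = 20L)
  cfg <- list(
    seed = seed,
    n_patients = as.integer(n_patients),
    study_period = study_period,
    surgery_concept_id = as.integer(surgery_concept_id),
    planted_cp = as_tibble(planted_cp),
    noise_orders = as_tibble(noise_orders),
    los_distribution = as_tibble(los_distribution),
    outpatient = utils::modifyList(op_defaults, outpatient),
    er = utils::modifyList(er_defaults, er),
    journey = utils::modifyList(jn_defaults, journey)
  )
  class(cfg) <- c("synthetic_config", "list")
  validate_synthetic_config(cfg)
  cfg
}

default_planted_cp <- function(n) {
  days <- sort(rep(c(-1L, 0L, 1L, 2L), length.out = n))
  tibble(
    relative_day = days,
    concept_id = 5000000L + seq_len(n),
    source_table = rep(c("drug_exposure", "measurement", "procedure_occurrence"),
                       length.out = n),
    occurrence_probability = round(runif(n, 0.85, 1.0), 3)
  )
}

default_noise_orders <- function(n) {
  tibble(
    concept_id = 6000000L + seq_len(n),
    source_table = rep(c("drug_exposure", "measurement", "procedure_occurrence",
                         "condition_occurrence", "observation"),
                       length.out = n),
    probability = round(runif(n, 0.01, 0.15), 4)
  )
}

default_journey_transition <- function() {
  states <- c("Outpatient", "Inpatient", "ER", "Checkup", "End")
  m <- matrix(c(
    # Out    In     ER    Check  End
    0.35,  0.20,  0.05,  0.05,  0.35,   # from Outpatient
    0.60,  0.05,  0.05,  0.05,  0.25,   # from Inpatient
    0.40,  0.20,  0.05,  0.05,  0.30,   # from ER
    0.40,  0.10,  0.05,  0.05,  0.40,   # from Checkup
    0,     0,     0,     0,     1.00    # End absorbing
  ), nrow = 5, byrow = TRUE, dimnames = list(states, states))
  m
}

validate_synthetic_config <- function(cfg) {
  stopifnot(cfg$n_patients >= 1L,
            length(cfg$study_period) == 2L,
            cfg$study_period[1] < cfg$study_period[2])
  p <- cfg$planted_cp$occurrence_probability
  if (any(p < 0 | p > 1)) abort("planted occurrence probabilities must lie in [0,1]")
  q <- cfg$noise_orders$probability
  if (any(q < 0 | q > 1)) abort("noise probabilities must lie in [0,1]")
  los <- cfg$los_distribution
  if (any(los$days < 1)) abort("length-of-stay support must be >= 1 day")
  if (abs(sum(los$prob) - 1) > 1e-9) abort("length-of-stay probabilities must sum to 1")
  # every planted day must fit inside every possible stay window
  if (nrow(cfg$planted_cp) > 0) {
    dmin <- min(cfg$planted_cp$relative_day)
    dmax <- max(cfg$planted_cp$relative_day)
    L <- min(los$days)
    lo <- max(1L, -dmin)
    hi <- min(L - 1L, L - dmax)
    if (lo > hi) {
      abort(paste0("planted relative days [", dmin, ", ", dmax, "] cannot fit ",
                   "inside a ", L, "-day stay with the operation after admission"))
    }
  }
  tm <- cfg$journey$transition
  if (any(abs(rowSums(tm) - 1) > 1e-9)) {
    abort("journey transition matrix rows must sum to 1")
  }
  for (d in list(cfg$er$source_distribution, cfg$er$discharge_distribution,
                 cfg$journey$initial)) {
    if (any(d < 0) || abs(sum(d) - 1) > 1e-9) {
      abort("distributions must be non-negative and sum to 1")
    }
  }
  if (!all(names(cfg$er$source_distribution) %in% as.character(er_source_concepts()))) {
    abort("er source distribution names unknown admission-source concept ids")
  }
  if (cfg$journey$cap < 1L) abort("visits_per_patient cap must be >= 1")
  invisible(cfg)
}

#' Read a synthetic-generator configuration from YAML
#'
#' Scalars and nested sections map one-to-one onto [synthetic_config()]
#' arguments; tabular fields (`planted_cp`, `noise_orders`,
#' `los_distribution`) are given as parallel lists.
#'
#' @param path YAML file.
#' @return A `synthetic_config`.
#' @export
read_synthetic_config <- function(path) {
  raw <- yaml::read_yaml(path)
  args <- list()
  for (nm in c("seed", "n_patients", "surgery_concept_id", "n_planted", "n_noise")) {
    if (!is.null(raw[[nm]])) args[[nm]] <- raw[[nm]]
  }
  if (!is.null(raw$study_period)) args$study_period <- as.Date(unlist(raw$study_period))
  for (nm in c("planted_cp", "noise_orders", "los_distribution")) {
    if (!is.null(raw[[nm]])) args[[nm]] <- as_tibble(lapply(raw[[nm]], unlist))
  }
  for (nm in c("outpatient", "er", "journey")) {
    if (!is.null(raw[[nm]])) {
      sec <- raw[[nm]]
      sec <- lapply(sec, function(x) if (is.list(x)) unlist(x) else x)
      if (nm == "journey" && !is.null(sec$transition)) {
        tm <- do.call(rbind, raw$journey$transition)
        states <- c("Outpatient", "Inpatient", "ER", "Checkup", "End")
        dimnames(tm) <- list(states, states)
        sec$transition <- tm
      }
      args[[nm]] <- sec
    }
  }
  do.call(synthetic_config, args)
}
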