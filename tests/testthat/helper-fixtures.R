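# Fixtures built in code: a tiny hand-written CDM, log builders, and random
# case-profile instances for property-style tests.

ts <- function(x) as.POSIXct(x, tz = "UTC")

# Two persons, one inpatient + one outpatient + one ER visit, events drawn
# from the built-in vocabulary.
tiny_cdm <- function() {
  cdm_dataset(
    person = tibble::tibble(
      person_id = c(1L, 2L),
      gender_concept_id = c(8532L, 8507L),
      year_of_birth = c(1981L, 1971L)),
    visit_occurrence = tibble::tibble(
      visit_occurrence_id = c(10L, 20L, 30L),
      person_id = c(1L, 2L, 1L),
      visit_concept_id = c(9201L, 9202L, 9203L),
      visit_start_datetime = ts(c("2021-08-01 09:03:00", "2021-08-01 10:00:00",
                                  "2021-08-01 19:04:00")),
      visit_end_datetime = ts(c("2021-08-04 10:00:00", "2021-08-01 12:00:00",
                                "2021-08-01 20:04:00")),
      provider_id = c(1L, 2L, 3L),
      care_site_id = c(1L, 1L, 1L),
      admitting_source_concept_id = c(NA, NA, 8536L),
      discharge_to_concept_id = c(NA, NA, 8536L)),
    procedure_occurrence = tibble::tibble(
      procedure_occurrence_id = 1L,
      visit_occurrence_id = 10L, person_id = 1L,
      procedure_concept_id = 4300001L,
      procedure_datetime = ts("2021-08-02 09:30:00"),
      date_only = FALSE, provider_id = 1L),
    drug_exposure = tibble::tibble(
      drug_exposure_id = 1:5,
      visit_occurrence_id = c(10L, 10L, 10L, 10L, 20L),
      person_id = c(1L, 1L, 1L, 1L, 2L),
      drug_concept_id = c(1154186L, 19086213L, 35605373L, 35605994L, 1154186L),
      drug_exposure_start_datetime = ts(c(
        "2021-08-01 09:03:00", "2021-08-01 10:01:00", "2021-08-02 09:45:00",
        "2021-08-03 08:30:00", "2021-08-01 10:25:00")),
      date_only = FALSE, provider_id = c(1L, 2L, 1L, 1L, 2L)),
    measurement = tibble::tibble(
      measurement_id = 1:3,
      visit_occurrence_id = c(10L, 10L, 30L),
      person_id = c(1L, 1L, 1L),
      measurement_concept_id = c(3012608L, 3013869L, 3012608L),
      measurement_datetime = ts(c("2021-08-01 12:30:00", "2021-08-01 12:35:00",
                                  "2021-08-01 19:31:00")),
      date_only = FALSE, provider_id = c(3L, 4L, 3L)),
    condition_occurrence = tibble::tibble(
      condition_occurrence_id = 1L,
      visit_occurrence_id = 20L, person_id = 2L,
      condition_concept_id = 40318361L,
      condition_start_datetime = ts("2021-08-01 10:04:00"),
      date_only = FALSE, provider_id = 2L),
    cost = tibble::tibble(
      cost_id = 1L, visit_occurrence_id = 20L, person_id = 2L,
      cost_concept_id = 40318361L, cost_datetime = ts("2021-08-01 11:50:00"),
      date_only = FALSE, provider_id = NA_integer_),
    provider = tibble::tibble(
      provider_id = 1:4, provider_name = paste0("prov", 1:4),
      care_site_id = 1L),
    care_site = tibble::tibble(care_site_id = 1L,
                               care_site_name = "Gynecology Dept."),
    concept = dplyr::bind_rows(
      base_concepts(),
      tibble::tibble(concept_id = 4300001L,
                     concept_name = "Total laparoscopic hysterectomy (synthetic)",
                     domain_id = "Procedure"))
  )
}

full_period <- function() ts(c("2018-01-01 00:00:00", "2030-01-01 00:00:00"))

# Build an event log from a list of activity vectors, one trace per element;
# events are spaced hourly from a per-case start.
mk_log <- function(traces, starts = NULL, process_type = "generic") {
  n <- length(traces)
  if (is.null(starts)) starts <- rep(ts("2021-08-01 09:00:00"), n)
  rows <- list()
  eid <- 0L
  for (i in seq_len(n)) {
    acts <- traces[[i]]
    for (j in seq_along(acts)) {
      eid <- eid + 1L
      rows[[eid]] <- tibble::tibble(
        case_id = paste0("c", i), event_id = paste0("e", eid),
        activity = acts[j], timestamp = starts[i] + (j - 1) * 3600)
    }
  }
  event_log(dplyr::bind_rows(rows), process_type = process_type)
}

# Random case-profile instance: every case gets >= 1 entry.
random_profiles <- function(n_cases = 20, n_concepts = 10, n_days = 3,
                            max_entries = 8) {
  rows <- list()
  for (i in seq_len(n_cases)) {
    k <- sample(1:max_entries, 1)
    rows[[i]] <- tibble::tibble(
      case_id = paste0("c", i),
      relative_day = sample(0:(n_days - 1), k, replace = TRUE),
      concept_id = sample(seq_len(n_concepts), k, replace = TRUE),
      source_table = "drug_exposure")
  }
  case_profiles(dplyr::bind_rows(rows),
                case_ids = paste0("c", seq_len(n_cases)))
}

random_cp <- function(profiles, k = 3) {
  cand <- dplyr::distinct(tibble::as_tibble(profiles)[
    , c("relative_day", "concept_id", "source_table")])
  cand[sample(nrow(cand), min(k, nrow(cand))), ]
}

# Separated instance: `k_true` strong entries present in most cases, weak
# noise entries, and a constant per-case profile size so that the greedy
# top-k coincides with the exhaustive optimum.
separated_profiles <- function(n_cases = 30, k_true = 3, n_noise = 6) {
  rows <- list()
  for (i in seq_len(n_cases)) {
    strong <- seq_len(k_true)           # present in ~every case
    weak <- k_true + sample(n_noise, 2) # rate <= 2/n_noise spread
    rows[[i]] <- tibble::tibble(
      case_id = paste0("c", i),
      relative_day = 0L,
      concept_id = as.integer(c(strong, weak)),
      source_table = "drug_exposure")
  }
  case_profiles(dplyr::bind_rows(rows),
                case_ids = paste0("c", seq_len(n_cases)))
}

# One patient with four visits in the Table-5 pattern: outpatient, laboratory,
# emergency room, inpatient; the outpatient visit carries two same-day drug
# rows for dedup checks and the inpatient visit holds the surgery.
journey_cdm <- function() {
  d <- tiny_cdm()
  d$visit_occurrence <- tibble::tibble(
    visit_occurrence_id = 1:4, person_id = 1L,
    visit_concept_id = c(9202L, 32036L, 9203L, 9201L),
    visit_start_datetime = ts(c("2021-08-01 09:04:00", "2021-08-01 10:04:00",
                                "2021-09-11 12:04:00", "2021-09-14 14:04:00")),
    visit_end_datetime = ts(c("2021-08-01 09:34:00", "2021-08-01 11:04:00",
                              "2021-09-11 16:04:00", "2021-09-20 10:04:00")),
    admitting_source_concept_id = c(NA, NA, 8536L, NA),
    discharge_to_concept_id = c(NA, NA, 8536L, NA))
  d$procedure_occurrence <- tibble::tibble(
    procedure_occurrence_id = 1L, visit_occurrence_id = 4L, person_id = 1L,
    procedure_concept_id = 4300001L,
    procedure_datetime = ts("2021-09-15 09:30:00"), date_only = FALSE)
  d$drug_exposure <- tibble::tibble(
    drug_exposure_id = 1:3, visit_occurrence_id = c(1L, 1L, 4L), person_id = 1L,
    drug_concept_id = c(1154186L, 19086213L, 35605373L),
    drug_exposure_start_datetime = ts(c("2021-08-01 09:10:00",
                                        "2021-08-01 09:20:00",
                                        "2021-09-15 11:00:00")),
    date_only = FALSE)
  d$measurement <- d$measurement[0, ]
  d$condition_occurrence <- d$condition_occurrence[0, ]
  d$cost <- d$cost[0, ]
  d
}
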