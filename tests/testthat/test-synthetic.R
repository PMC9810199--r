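test_that("generators are deterministic under a fixed seed", {
  cfg <- synthetic_config(seed = 7, n_patients = 6)
  for (type in c("inpatient", "outpatient", "er", "patient_journey")) {
    a <- simulate_cdm(cfg, type)
    b <- simulate_cdm(cfg, type)
    for (tb in names(a$dataset)) {
      expect_identical(a$dataset[[tb]], b$dataset[[tb]], info = paste(type, tb))
    }
    expect_identical(a$truth[setdiff(names(a$truth), "transition")],
                     b$truth[setdiff(names(b$truth), "transition")])
  }
})

test_that("per-patient sub-streams keep early patients stable as n grows", {
  small <- generate_inpatient_cohort(synthetic_config(seed = 3, n_patients = 4))
  large <- generate_inpatient_cohort(synthetic_config(seed = 3, n_patients = 8))
  expect_identical(small$dataset$visit_occurrence,
                   large$dataset$visit_occurrence[1:4, ])
})

test_that("every generator output passes CDM validation", {
  cfg <- synthetic_config(seed = 5, n_patients = 10)
  for (type in c("inpatient", "outpatient", "er", "patient_journey")) {
    sim <- simulate_cdm(cfg, type)
    expect_equal(nrow(validate_cdm(sim$dataset)), 0, info = type)
  }
})

test_that("probability-1 planted entries occur in every case on the operation day", {
  planted <- tibble::tibble(relative_day = 0L, concept_id = 5000001L,
                            source_table = "drug_exposure",
                            occurrence_probability = 1.0)
  cfg <- synthetic_config(seed = 9, n_patients = 25, planted_cp = planted,
                          noise_orders = tibble::tibble(
                            concept_id = integer(0), source_table = character(0),
                            probability = numeric(0)))
  sim <- generate_inpatient_cohort(cfg)
  drugs <- sim$dataset$drug_exposure
  anchors <- sim$truth$anchors
  hit <- dplyr::inner_join(drugs, anchors, by = "visit_occurrence_id") |>
    dplyr::filter(drug_concept_id == 5000001L,
                  as.Date(drug_exposure_start_datetime, tz = "UTC") == anchor_date)
  expect_setequal(hit$visit_occurrence_id, anchors$visit_occurrence_id)
})

test_that("empirical planted application rate converges to the configured probability", {
  planted <- tibble::tibble(relative_day = 0L, concept_id = 5000001L,
                            source_table = "drug_exposure",
                            occurrence_probability = 0.7)
  cfg <- synthetic_config(seed = 13, n_patients = 2000, planted_cp = planted,
                          noise_orders = tibble::tibble(
                            concept_id = integer(0), source_table = character(0),
                            probability = numeric(0)))
  sim <- generate_inpatient_cohort(cfg)
  anchors <- sim$truth$anchors
  hits <- dplyr::inner_join(sim$dataset$drug_exposure, anchors,
                            by = "visit_occurrence_id") |>
    dplyr::filter(as.Date(drug_exposure_start_datetime, tz = "UTC") == anchor_date)
  frac <- length(unique(hits$visit_occurrence_id)) / 2000
  se <- sqrt(0.7 * 0.3 / 2000)
  expect_lt(abs(frac - 0.7), 3 * se)
})

test_that("each inpatient case has exactly one surgery event after admission", {
  sim <- generate_inpatient_cohort(synthetic_config(seed = 21, n_patients = 15))
  surg <- sim$dataset$procedure_occurrence |>
    dplyr::filter(procedure_concept_id == sim$truth$surgery_concept_id)
  expect_equal(sort(surg$visit_occurrence_id), 1:15)
  v <- sim$dataset$visit_occurrence
  op_day <- as.Date(surg$procedure_datetime[order(surg$visit_occurrence_id)],
                    tz = "UTC")
  adm_day <- as.Date(v$visit_start_datetime, tz = "UTC")
  expect_true(all(op_day >= adm_day + 1))
})

test_that("outpatient date-only degradation follows the configured fraction", {
  cfg1 <- synthetic_config(seed = 8, n_patients = 10,
                           outpatient = list(date_only_fraction = c(cost = 1.0)))
  sim1 <- generate_outpatient_visits(cfg1)
  expect_true(all(sim1$dataset$cost$date_only))
  expect_false(any(sim1$dataset$drug_exposure$date_only))
  cfg0 <- synthetic_config(seed = 8, n_patients = 10,
                           outpatient = list(date_only_fraction = c(cost = 0)))
  sim0 <- generate_outpatient_visits(cfg0)
  expect_false(any(sim0$dataset$cost$date_only))
  # with nothing date-only, timestamp repair is a no-op downstream
  spec <- log_spec("outpatient", period = full_period())
  log <- extract_outpatient_log(sim0$dataset, spec)
  expect_identical(tidy(repair_dateonly_timestamps(log)), tidy(log))
})

test_that("outpatient per-table event counts track the configured means", {
  cfg <- synthetic_config(seed = 17, n_patients = 150)
  sim <- generate_outpatient_visits(cfg)
  counts <- sim$truth$per_visit_counts
  n_vis <- sim$truth$n_visits
  for (tb in names(sim$truth$event_means)) {
    m <- sim$truth$event_means[[tb]]
    total <- sum(counts$n[counts$source_table == tb])
    se <- sqrt(m / n_vis)  # Poisson
    expect_lt(abs(total / n_vis - m), 3 * se, label = tb)
  }
})

test_that("a degenerate ER source distribution sends every visit from home", {
  cfg <- synthetic_config(seed = 4, n_patients = 12,
                          er = list(source_distribution = c("8536" = 1)))
  sim <- generate_er_visits(cfg)
  expect_true(all(sim$dataset$visit_occurrence$admitting_source_concept_id == 8536L))
})

test_that("ER stay durations match the configured moments", {
  cfg <- synthetic_config(seed = 19, n_patients = 400)
  sim <- generate_er_visits(cfg)
  v <- sim$dataset$visit_occurrence
  los_h <- as.double(v$visit_end_datetime - v$visit_start_datetime,
                     units = "secs") / 3600
  se <- sim$truth$sd_los_hours / sqrt(nrow(v))
  expect_lt(abs(mean(los_h) - sim$truth$mean_los_hours), 3 * se)
})

test_that("a forced Outpatient -> Inpatient -> End chain yields identical traces", {
  states <- c("Outpatient", "Inpatient", "ER", "Checkup", "End")
  tm <- matrix(0, 5, 5, dimnames = list(states, states))
  tm["Outpatient", "Inpatient"] <- 1
  tm["Inpatient", "End"] <- 1
  tm["ER", "End"] <- 1; tm["Checkup", "End"] <- 1; tm["End", "End"] <- 1
  cfg <- synthetic_config(seed = 2, n_patients = 10,
                          journey = list(initial = c(Outpatient = 1, Inpatient = 0,
                                                     ER = 0, Checkup = 0, End = 0),
                                         transition = tm))
  sim <- generate_patient_journeys(cfg)
  seqs <- sim$truth$sequences |>
    dplyr::group_by(person_id) |>
    dplyr::summarise(trace = paste(visit_type, collapse = ","))
  expect_true(all(seqs$trace == "Outpatient,Inpatient"))
})

test_that("empirical journey transition frequencies match the chain", {
  cfg <- synthetic_config(seed = 23, n_patients = 1000)
  sim <- generate_patient_journeys(cfg)
  seqs <- sim$truth$sequences
  tm <- sim$truth$transition
  # observed next state; terminal steps below the cap are true -> End moves,
  # cap-truncated finals are censored
  obs <- seqs |>
    dplyr::group_by(person_id) |>
    dplyr::mutate(next_type = dplyr::coalesce(dplyr::lead(visit_type),
                                              ifelse(dplyr::n() < 20, "End", NA))) |>
    dplyr::ungroup() |>
    dplyr::filter(!is.na(next_type))
  for (from in c("Outpatient", "Inpatient", "ER", "Checkup")) {
    of <- obs[obs$visit_type == from, ]
    if (nrow(of) < 30) next
    for (to in colnames(tm)) {
      p <- tm[from, to]
      phat <- mean(of$next_type == to)
      se <- sqrt(max(p * (1 - p), 1e-12) / nrow(of))
      expect_lt(abs(phat - p), 3 * se + 1e-9,
                label = paste(from, "->", to))
    }
  }
})

test_that("journey visit windows never overlap within a patient", {
  sim <- generate_patient_journeys(synthetic_config(seed = 6, n_patients = 40))
  v <- sim$dataset$visit_occurrence |>
    dplyr::arrange(person_id, visit_start_datetime) |>
    dplyr::group_by(person_id) |>
    dplyr::mutate(prev_end = dplyr::lag(visit_end_datetime)) |>
    dplyr::ungroup()
  ok <- is.na(v$prev_end) | v$visit_start_datetime > v$prev_end
  expect_true(all(ok))
})

test_that("infeasible planted days are a fatal configuration error", {
  expect_error(
    synthetic_config(seed = 1, n_patients = 5,
                     planted_cp = tibble::tibble(
                       relative_day = 10L, concept_id = 5000001L,
                       source_table = "drug_exposure",
                       occurrence_probability = 0.9)),
    "cannot fit")
})
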