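inpatient_spec <- function(...) {
  log_spec("inpatient", period = full_period(), ...)
}

test_that("select_cohort filters by visit concept, period and cohort events", {
  d <- tiny_cdm()
  # only visit 10 is inpatient and contains the surgery concept
  spec <- inpatient_spec(cohort = list(table = "procedure_occurrence",
                                       concept_ids = 4300001L))
  expect_equal(select_cohort(d, spec), 10L)
  # a period excluding every visit selects nothing
  late <- log_spec("inpatient", period = ts(c("2025-01-01", "2026-01-01")))
  expect_warning(out <- select_cohort(d, late), "no visits")
  expect_length(out, 0)
})

test_that("cohort selection counts qualifying visits exactly", {
  d <- tiny_cdm()
  # 5 inpatient visits, 3 with the surgery concept
  d$visit_occurrence <- tibble::tibble(
    visit_occurrence_id = 1:5, person_id = 1L, visit_concept_id = 9201L,
    visit_start_datetime = ts(paste0("2021-0", 1:5, "-01 08:00:00")),
    visit_end_datetime = ts(paste0("2021-0", 1:5, "-05 08:00:00")))
  d$procedure_occurrence <- tibble::tibble(
    procedure_occurrence_id = 1:3, visit_occurrence_id = c(1L, 3L, 5L),
    person_id = 1L, procedure_concept_id = 4300001L,
    procedure_datetime = ts(paste0("2021-0", c(1, 3, 5), "-02 09:00:00")),
    date_only = FALSE)
  d$drug_exposure <- d$drug_exposure[0, ]
  d$measurement <- d$measurement[0, ]
  spec <- inpatient_spec(cohort = list(table = "procedure_occurrence",
                                       concept_ids = 4300001L))
  expect_equal(select_cohort(d, spec), c(1L, 3L, 5L))
})

test_that("use_descendants expands the cohort concept set", {
  d <- tiny_cdm()
  d$concept_ancestor <- tibble::tibble(
    ancestor_concept_id = c(4000L, 4000L), descendant_concept_id = c(4000L, 4300001L))
  # visit 10 has only the descendant concept 4300001
  spec <- inpatient_spec(cohort = list(table = "procedure_occurrence",
                                       concept_ids = 4000L,
                                       use_descendants = TRUE))
  expect_equal(select_cohort(d, spec), 10L)
  spec_plain <- inpatient_spec(cohort = list(table = "procedure_occurrence",
                                             concept_ids = 4000L))
  expect_warning(out <- select_cohort(d, spec_plain), "no visits")
  expect_length(out, 0)
})

test_that("compute_los follows calendar days and exact hours", {
  v <- tibble::tibble(
    visit_start_datetime = ts(c("2021-08-01 09:03:00", "2021-08-01 09:00:00",
                                "2021-08-01 19:04:00")),
    visit_end_datetime = ts(c("2021-08-04 10:00:00", "2021-08-01 09:00:00",
                              "2021-08-01 20:04:00")))
  expect_equal(compute_los(v, "days"), c(3L, 0L, 0L))
  expect_equal(compute_los(v, "hours")[3], 1.00)
  bad <- tibble::tibble(visit_start_datetime = ts("2021-08-02 00:00:00"),
                        visit_end_datetime = ts("2021-08-01 00:00:00"))
  expect_error(compute_los(bad, "days"), "corrupt")
})

test_that("inpatient extraction renders activities, scope, and case attributes", {
  d <- tiny_cdm()
  spec <- inpatient_spec(scope = "drug_exposure")
  log <- extract_inpatient_log(d, spec)
  ev <- tidy(log)
  # visit 10 has 4 drug rows and 2 measurement rows; scope keeps the drugs
  expect_equal(nrow(ev), 4)
  expect_true(all(ev$source_table == "drug_exposure"))
  expect_equal(ev$activity[1], "1154186 (fentanyl 0.1 MG)")
  cases <- log_cases(log)
  expect_equal(cases$los_days, 3L)
  expect_equal(cases$sex, "8532 (Female)")
  expect_equal(cases$age, 40L)
})

test_that("extraction conserves scoped CDM rows and carries their identity", {
  sim <- generate_inpatient_cohort(synthetic_config(seed = 31, n_patients = 12))
  d <- sim$dataset
  spec <- inpatient_spec()
  log <- extract_inpatient_log(d, spec)
  scoped <- omopflow:::cdm_events(d, spec$scope)
  expect_equal(nrow(log), nrow(scoped))
  expect_setequal(paste(tidy(log)$source_table, tidy(log)$event_row_id),
                  paste(scoped$source_table, scoped$event_row_id))
  # LOS case attribute equals the calendar-day difference of the visit record
  v <- d$visit_occurrence
  expect_equal(log_cases(log)$los_days[match(v$visit_occurrence_id,
                                             log_cases(log)$case_id)],
               compute_los(v, "days"))
})

test_that("outpatient activities use the table-level mapping", {
  d <- tiny_cdm()
  d$observation <- tibble::tibble(
    observation_id = 1L, visit_occurrence_id = 20L, person_id = 2L,
    observation_concept_id = 40318361L,
    observation_datetime = ts("2021-08-01 11:00:00"),
    date_only = FALSE, provider_id = 2L)
  spec <- log_spec("outpatient", period = full_period(),
                   features = "department")
  log <- extract_outpatient_log(d, spec)
  ev <- tidy(log)
  expect_setequal(ev$activity, c("Consultation", "Drug", "Survey", "Payment"))
  expect_equal(ev$activity[ev$source_table == "condition_occurrence"], "Consultation")
  expect_equal(ev$activity[ev$source_table == "cost"], "Payment")
  expect_equal(ev$activity[ev$source_table == "observation"], "Survey")
  expect_true("department" %in% names(ev))
})

test_that("timestamp repair orders condition > drug > cost with linear gaps", {
  base <- ts("2021-08-01 10:00:00")
  events <- tibble::tibble(
    case_id = "c1",
    event_id = c("m1", "co1", "d1", "cost1"),
    activity = c("Physical examination & Lab test", "Consultation", "Drug", "Payment"),
    timestamp = c(base, rep(ts("2021-08-01 00:00:00"), 3)),
    source_table = c("measurement", "condition_occurrence", "drug_exposure", "cost"),
    event_row_id = 1:4,
    date_only = c(FALSE, TRUE, TRUE, TRUE))
  log <- event_log(events, process_type = "outpatient")
  rep <- repair_dateonly_timestamps(log)
  ev <- tidy(rep)
  # timed events unmoved
  expect_equal(ev$timestamp[ev$event_id == "m1"], base)
  # repaired order: condition, drug, cost after the day's last timed event
  repaired <- ev[ev$date_only, ]
  expect_equal(repaired$source_table,
               c("condition_occurrence", "drug_exposure", "cost"))
  gaps_min <- as.double(diff(c(base, repaired$timestamp)), units = "mins")
  # K = 3 in [5, 30] -> successive gaps 5, 17.5, 30 minutes
  expect_equal(gaps_min, c(5, 17.5, 30))
  expect_true(all(gaps_min >= 5 & gaps_min <= 30))
})

test_that("a single date-only event lands one minimum gap after the base", {
  events <- tibble::tibble(
    case_id = "c1", event_id = "cost1", activity = "Payment",
    timestamp = ts("2021-08-01 00:00:00"), source_table = "cost",
    event_row_id = 1L, date_only = TRUE)
  log <- event_log(events)
  rep <- repair_dateonly_timestamps(log)
  # no timed event that day: base is 09:00
  expect_equal(tidy(rep)$timestamp, ts("2021-08-01 09:05:00"))
})

test_that("repair rejects date-only tables missing from the priority order", {
  events <- tibble::tibble(
    case_id = "c1", event_id = "o1", activity = "Survey",
    timestamp = ts("2021-08-01 00:00:00"), source_table = "observation",
    event_row_id = 1L, date_only = TRUE)
  expect_error(repair_dateonly_timestamps(event_log(events)), "observation")
})

test_that("ER logs start with the admission source and end with the discharge", {
  d <- tiny_cdm()
  spec <- log_spec("er", period = full_period())
  log <- extract_er_log(d, spec)
  ev <- tidy(log)
  expect_equal(ev$activity[1], "8536 (Visit from home)")
  expect_equal(ev$activity[nrow(ev)], "8536 (Discharge to home)")
  expect_equal(ev$timestamp[nrow(ev)], ts("2021-08-01 20:04:00"))
  expect_equal(log_cases(log)$los_hours, 1.00)
  # hospital-to-hospital transfer rendering
  d$visit_occurrence$admitting_source_concept_id[3] <- 44790567L
  ev2 <- tidy(extract_er_log(d, spec))
  expect_equal(ev2$activity[1],
               "44790567 (Patient transfer from hospital to hospital)")
})

test_that("visit-level journeys reproduce the visit-type trace", {
  d <- journey_cdm()
  spec <- log_spec("patient_journey", period = full_period())
  log <- extract_patient_journey_log(d, spec)
  expect_equal(tidy(log)$activity,
               c("Outpatient visit", "Laboratory visit",
                 "Emergency room visit", "Inpatient visit"))
  expect_equal(tidy(log)$visit_index, rep(1L, 4))
})

test_that("descendant-level journeys index visits per type and dedup by day", {
  d <- journey_cdm()
  spec <- log_spec("patient_journey", period = full_period(),
                   journey_level = "descendant")
  log <- extract_patient_journey_log(d, spec)
  ev <- tidy(log)
  # two same-day drug rows in outpatient visit 1 collapse to one Out_1_Drug
  expect_equal(sum(ev$activity == "Out_1_Drug"), 1)
  expect_equal(ev$event_id[ev$activity == "Out_1_Drug"], "drug_exposure_1")
  expect_true(all(c("In_1_Procedure", "In_1_Drug") %in% ev$activity))
  # dedup equals the brute-force first-per-(label, date) filter
  raw <- omopflow:::cdm_events(d, spec$scope)
  expect_equal(nrow(ev), nrow(dplyr::distinct(
    dplyr::mutate(raw, day = as.Date(event_datetime, tz = "UTC")),
    visit_occurrence_id, source_table, day)))
})

test_that("per-type journey indices increase chronologically", {
  d <- journey_cdm()
  # three outpatient visits
  d$visit_occurrence <- dplyr::bind_rows(
    d$visit_occurrence,
    tibble::tibble(visit_occurrence_id = 5:6, person_id = 1L,
                   visit_concept_id = 9202L,
                   visit_start_datetime = ts(c("2021-10-01 09:00:00",
                                               "2021-11-01 09:00:00")),
                   visit_end_datetime = ts(c("2021-10-01 10:00:00",
                                             "2021-11-01 10:00:00"))))
  spec <- log_spec("patient_journey", period = full_period())
  ev <- tidy(extract_patient_journey_log(d, spec))
  out_idx <- ev$visit_index[ev$activity == "Outpatient visit"]
  expect_equal(out_idx, 1:3)
})

test_that("journey markers wrap each visit at descendant level", {
  d <- journey_cdm()
  spec <- log_spec("patient_journey", period = full_period(),
                   journey_level = "descendant", journey_markers = TRUE)
  ev <- tidy(extract_patient_journey_log(d, spec))
  expect_true(all(c("Out_1_Start", "Out_1_End", "In_1_Start", "In_1_End")
                  %in% ev$activity))
  # start marker precedes the visit's clinical events
  expect_lt(which(ev$activity == "Out_1_Start"),
            which(ev$activity == "Out_1_Drug"))
})

test_that("event logs round trip through CSV and XES", {
  d <- tiny_cdm()
  log <- extract_er_log(d, log_spec("er", period = full_period()))
  for (fmt in c("csv", "xes")) {
    path <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_log(log, path, format = fmt)
    back <- read_log(path, format = fmt)
    expect_equal(log_process_type(back), "er")
    a <- tidy(log); b <- tidy(back)[, names(tidy(log))]
    expect_equal(as.data.frame(b), as.data.frame(a), ignore_attr = TRUE,
                 info = fmt)
    ca <- log_cases(log); cb <- log_cases(back)[, names(log_cases(log))]
    expect_equal(as.data.frame(cb), as.data.frame(ca), ignore_attr = TRUE,
                 info = fmt)
  }
})

test_that("within-case events are non-decreasing in time after repair", {
  sim <- generate_outpatient_visits(synthetic_config(seed = 37, n_patients = 15))
  log <- extract_outpatient_log(sim$dataset,
                                log_spec("outpatient", period = full_period()))
  rep <- repair_dateonly_timestamps(log)
  ev <- tidy(rep)
  ok <- ev |>
    dplyr::group_by(case_id) |>
    dplyr::summarise(sorted = !is.unsorted(timestamp))
  expect_true(all(ok$sorted))
})
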