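#' Specify an event-log extraction
#'
#' Mirrors the five-element specification of a process-mining log over a CDM:
#' process type, period, scope (which activity tables contribute events),
#' fields (fixed: case id, event id, activity, timestamp, originator) and
#' optional features.
#'
#' @param process_type `"inpatient"`, `"outpatient"`, `"er"` or
#'   `"patient_journey"`.
#' @param period Length-2 POSIXct/Date vector, half-open `[start, end)`;
#'   visits belong to the period by `visit_start_datetime`.
#' @param scope Character vector of activity tables; defaults per process type
#'   (inpatient: measurement, drug_exposure, procedure_occurrence; outpatient:
#'   the six outpatient tables; ER: measurement, drug_exposure, observation,
#'   note; journey: all).
#' @param cohort Optional list `(table, concept_ids, use_descendants)` — the
#'   visit must contain at least one event of these concepts in that table.
#' @param features Character vector of optional attributes to attach
#'   (currently `"department"`).
#' @param include_262 Include visit concept 262 (shared ER + inpatient code)
#'   in inpatient and ER extraction.
#' @param er_activity Interior ER activities as `"table"` labels or
#'   `"concept"` renderings.
#' @param journey_level `"visit"` (one event per visit) or `"descendant"`
#'   (indexed within-visit activities).
#' @param journey_window Wider `[start, end)` within which all visits of a
#'   qualifying patient are kept; defaults to `period`.
#' @param journey_activity Descendant-level labels from the source `"table"`
#'   or the `"concept"` rendering.
#' @param journey_markers Append synthetic `<Type>_<k>_Start` / `_End`
#'   boundary events per visit at descendant level.
#' @return A `log_spec` list.
#' @export
log_spec <- function(process_type = c("inpatient", "outpatient", "er",
                                      "patient_journey"),
                     period,
                     scope = NULL,
                     cohort = NULL,
                     features = character(0),
                     include_262 = TRUE,
                     er_activity = c("table", "concept"),
                     journey_level = c("visit", "descendant"),
                     journey_window = NULL,
                     journey_activity = c("table", "concept"),
                     journey_markers = FALSE) {
  process_type <- match.arg(process_type)
  period <- as.POSIXct(period, tz = "UTC")
  if (length(period) != 2L || period[1] >= period[2]) {
    abort("period must be [start, end) with start < end")
  }
  if (is.null(scope)) {
    scope <- switch(process_type,
      inpatient = c("measurement", "drug_exposure", "procedure_occurrence"),
      outpatient = c("condition_occurrence", "measurement", "drug_exposure",
                     "procedure_occurrence", "cost", "observation"),
      er = c("measurement", "drug_exposure", "observation", "note"),
      patient_journey = cdm_event_tables())
  }
  if (length(scope) == 0) abort("scope must name at least one activity table")
  bad <- setdiff(scope, cdm_event_tables())
  if (length(bad) > 0) abort(paste0("unknown scope table(s): ", paste(bad, collapse = ", ")))
  if (!is.null(cohort)) {
    stopifnot(is.list(cohort), !is.null(cohort$table), !is.null(cohort$concept_ids))
    cohort$use_descendants <- isTRUE(cohort$use_descendants)
  }
  journey_window <- if (is.null(journey_window)) period else as.POSIXct(journey_window, tz = "UTC")
  if (journey_window[1] > period[1] || journey_window[2] < period[2]) {
    abort("journey_window must contain the period")
  }
  structure(list(
    process_type = process_type, period = period, scope = scope,
    cohort = cohort, features = features, include_262 = include_262,
    er_activity = match.arg(er_activity),
    journey_level = match.arg(journey_level),
    journey_window = journey_window,
    journey_activity = match.arg(journey_activity),
    journey_markers = journey_markers), class = "log_spec")
}

spec_visit_concepts <- function(spec) {
  switch(spec$process_type,
    inpatient = c(9201L, if (spec$include_262) 262L),
    outpatient = 9202L,
    er = c(9203L, if (spec$include_262) 262L),
    patient_journey = NULL)
}

cohort_concept_set <- function(dataset, cohort) {
  ids <- as.integer(cohort$concept_ids)
  if (isTRUE(cohort$use_descendants)) {
    ids <- sort(unique(unlist(lapply(ids, function(a) {
      suppressWarnings(concept_descendants(dataset, a))
    }))))
  }
  ids
}

#' Select the visit (or person) cohort of a log specification
#'
#' Visits of the specification's visit concept whose start falls in the period
#' and that contain at least one cohort event; multiple cohort concept ids are
#' OR-ed and optionally expanded through the concept hierarchy. For patient
#' journeys the persons owning a qualifying visit are returned instead.
#'
#' @param dataset A [cdm_dataset()].
#' @param spec A [log_spec()].
#' @return Integer vector of `visit_occurrence_id`s (person ids for journeys).
#' @export
select_cohort <- function(dataset, spec) {
  v <- dataset$visit_occurrence
  in_period <- v$visit_start_datetime >= spec$period[1] &
    v$visit_start_datetime < spec$period[2]
  vc <- spec_visit_concepts(spec)
  keep <- in_period & (if (is.null(vc)) TRUE else v$visit_concept_id %in% vc)
  vids <- v$visit_occurrence_id[keep]
  if (!is.null(spec$cohort)) {
    ids <- cohort_concept_set(dataset, spec$cohort)
    ev <- cdm_events(dataset, tables = spec$cohort$table)
    hit <- unique(ev$visit_occurrence_id[ev$concept_id %in% ids])
    vids <- intersect(vids, hit)
  }
  if (spec$process_type == "patient_journey") {
    pids <- sort(unique(v$person_id[v$visit_occurrence_id %in% vids]))
    if (length(pids) == 0) warn("cohort selection returned no persons")
    return(pids)
  }
  if (length(vids) == 0) warn("cohort selection returned no visits")
  sort(vids)
}

#' Length of stay of visits
#'
#' Days are the calendar-date difference between visit end and start (an
#' admission on Aug 1 discharged Aug 4 is 3 days regardless of clock times);
#' hours are the exact duration divided by 3600, rounded to two decimals.
#'
#' @param visit Tibble with `visit_start_datetime` / `visit_end_datetime`.
#' @param unit `"days"` or `"hours"`.
#' @return Numeric vector.
#' @export
#' @examples
#' v <- tibble::tibble(
#'   visit_start_datetime = as.POSIXct("2021-08-01 09:03:00", tz = "UTC"),
#'   visit_end_datetime = as.POSIXct("2021-08-04 10:00:00", tz = "UTC"))
#' compute_los(v, "days")
compute_los <- function(visit, unit = c("days", "hours")) {
  unit <- match.arg(unit)
  s <- visit$visit_start_datetime
  e <- visit$visit_end_datetime
  if (any(e < s)) abort("corrupt visit: visit_end_datetime earlier than visit_start_datetime")
  if (unit == "days") {
    as.integer(as.Date(e, tz = "UTC") - as.Date(s, tz = "UTC"))
  } else {
    round(as.double(e - s, units = "secs") / 3600, 2)
  }
}

person_case_attrs <- function(dataset, visits) {
  p <- dataset$person
  idx <- match(visits$person_id, p$person_id)
  tibble(
    person_id = visits$person_id,
    sex = resolve_concept(dataset, p$gender_concept_id[idx], style = "id_name"),
    age = as.integer(format(visits$visit_start_datetime, "%Y")) -
      p$year_of_birth[idx]
  )
}

event_ids <- function(source_table, event_row_id) {
  paste0(source_table, "_", event_row_id)
}

attach_department <- function(events, dataset) {
  prov <- dataset$provider
  cs <- dataset$care_site
  dep <- cs$care_site_name[match(prov$care_site_id, cs$care_site_id)]
  events$department <- dep[match(events$provider_id, prov$provider_id)]
  events
}

scoped_visit_events <- function(dataset, spec, vids) {
  ev <- cdm_events(dataset, tables = spec$scope) |>
    filter(.data$visit_occurrence_id %in% vids)
  ev
}

#' Extract an inpatient event log
#'
#' One case per selected inpatient visit (case id = visit occurrence id);
#' events are the scope-table rows of the visit with the
#' `"<concept_id> (<concept name>)"` activity rendering; case attributes carry
#' length of stay in days, sex and age at admission.
#'
#' @param dataset A [cdm_dataset()].
#' @param spec A [log_spec()] with `process_type = "inpatient"`.
#' @return An [event_log()].
#' @export
extract_inpatient_log <- function(dataset, spec) {
  stopifnot(spec$process_type == "inpatient")
  vids <- select_cohort(dataset, spec)
  v <- dataset$visit_occurrence |> filter(.data$visit_occurrence_id %in% vids)
  ev <- scoped_visit_events(dataset, spec, vids)
  events <- tibble(
    case_id = as.character(ev$visit_occurrence_id),
    event_id = event_ids(ev$source_table, ev$event_row_id),
    activity = resolve_concept(dataset, ev$concept_id, style = "id_name"),
    timestamp = ev$event_datetime,
    originator = ifelse(is.na(ev$provider_id), "", paste0("O", ev$provider_id)),
    source_table = ev$source_table,
    event_row_id = ev$event_row_id,
    concept_id = ev$concept_id,
    date_only = ev$date_only,
    provider_id = ev$provider_id)
  if ("department" %in% spec$features) events <- attach_department(events, dataset)
  events$provider_id <- NULL
  cases <- tibble(
    case_id = as.character(v$visit_occurrence_id),
    person_id = v$person_id,
    los_days = compute_los(v, "days")) |>
    bind_cols(person_case_attrs(dataset, v)[c("sex", "age")])
  empty <- setdiff(cases$case_id, events$case_id)
  if (length(empty) > 0) {
    warn(paste0(length(empty), " case(s) have no scoped events"))
  }
  event_log(events, cases = cases, process_type = "inpatient")
}

#' Extract an outpatient event log
#'
#' One case per outpatient visit; activities are the table-level labels
#' (condition -> Consultation, measurement -> Physical examination & Lab test,
#' drug -> Drug, procedure -> Surgery & Radiology test, cost -> Payment,
#' observation -> Survey). Date-only rows keep their flag so that
#' [repair_dateonly_timestamps()] can re-sequence them.
#'
#' @inheritParams extract_inpatient_log
#' @return An [event_log()].
#' @export
extract_outpatient_log <- function(dataset, spec) {
  stopifnot(spec$process_type == "outpatient")
  vids <- select_cohort(dataset, spec)
  v <- dataset$visit_occurrence |> filter(.data$visit_occurrence_id %in% vids)
  ev <- scoped_visit_events(dataset, spec, vids)
  labels <- outpatient_table_labels()
  events <- tibble(
    case_id = as.character(ev$visit_occurrence_id),
    event_id = event_ids(ev$source_table, ev$event_row_id),
    activity = unname(labels[ev$source_table]),
    timestamp = ev$event_datetime,
    originator = ifelse(is.na(ev$provider_id), "", paste0("O", ev$provider_id)),
    source_table = ev$source_table,
    event_row_id = ev$event_row_id,
    concept_id = ev$concept_id,
    date_only = ev$date_only,
    provider_id = ev$provider_id)
  if ("department" %in% spec$features) events <- attach_department(events, dataset)
  events$provider_id <- NULL
  cases <- tibble(case_id = as.character(v$visit_occurrence_id),
                  person_id = v$person_id) |>
    bind_cols(person_case_attrs(dataset, v)[c("sex", "age")])
  event_log(events, cases = cases, process_type = "outpatient")
}

#' Deterministically re-time date-only events
#'
#' Within each case and calendar day, events that carried only a calendar date
#' are re-timestamped after the day's last timed event (09:00 if the day has
#' none), sequenced by the given source-table priority (default condition >
#' drug > cost), with successive gaps spread linearly across
#' `gap_minutes = [min, max]`: for `K` repaired events the k-th gap is
#' `min + (max - min) * (k - 1) / max(1, K - 1)` minutes. Timed events are
#' never moved.
#'
#' @param log An [event_log()].
#' @param order Source tables in repair priority order; must cover every
#'   date-only event's table.
#' @param gap_minutes Length-2 numeric `[min, max]`, `0 < min <= max`.
#' @return The re-sorted [event_log()].
#' @export
repair_dateonly_timestamps <- function(log,
                                       order = c("condition_occurrence",
                                                 "drug_exposure", "cost"),
                                       gap_minutes = c(5, 30)) {
  stopifnot(inherits(log, "event_log"),
            length(gap_minutes) == 2L,
            gap_minutes[1] > 0, gap_minutes[1] <= gap_minutes[2])
  events <- tidy(log)
  is_do <- events$date_only %in% TRUE
  if (!any(is_do)) return(log)
  uncovered <- setdiff(unique(events$source_table[is_do]), order)
  if (length(uncovered) > 0) {
    abort(paste0("date-only events from table(s) not covered by the repair order: ",
                 paste(uncovered, collapse = ", ")))
  }
  events$.day <- as.Date(events$timestamp, tz = "UTC")
  groups <- events |>
    filter(is_do) |>
    distinct(.data$case_id, .data$.day)
  for (g in seq_len(nrow(groups))) {
    sel <- which(events$case_id == groups$case_id[g] &
                   events$.day == groups$.day[g] & is_do)
    timed <- events$timestamp[events$case_id == groups$case_id[g] &
                                events$.day == groups$.day[g] & !is_do]
    base <- if (length(timed) > 0) max(timed) else
      as.POSIXct(paste(groups$.day[g], "09:00:00"), tz = "UTC")
    sel <- sel[order(match(events$source_table[sel], order),
                     events$event_row_id[sel])]
    K <- length(sel)
    gaps <- gap_minutes[1] +
      (gap_minutes[2] - gap_minutes[1]) * (seq_len(K) - 1) / max(1, K - 1)
    events$timestamp[sel] <- base + cumsum(gaps) * 60
  }
  events$.day <- NULL
  event_log(events, cases = log_cases(log), process_type = log_process_type(log))
}

er_admission_label <- function(dataset, concept_id) {
  out <- resolve_concept(dataset, concept_id, style = "id_name")
  out[is.na(concept_id)] <- "unknown source"
  out
}

er_discharge_label <- function(dataset, concept_id) {
  nm <- resolve_concept(dataset, concept_id, style = "name")
  dest <- sub("^(Visit from|Transfer from|Patient transfer from)\\s+", "", nm)
  dest <- ifelse(dest == nm, nm, dest)
  out <- paste0(concept_id, " (Discharge to ", dest, ")")
  out[is.na(concept_id)] <- "unknown destination"
  out
}

#' Extract an emergency-room event log
#'
#' Per case, the first event is the admitting-source activity at visit start
#' (e.g. `"8536 (Visit from home)"`) and the last the discharge activity at
#' visit end (`"8536 (Discharge to home)"`); interior events come from the
#' scoped tables with table-level or concept-level labels. Length of stay in
#' hours is a case attribute.
#'
#' @inheritParams extract_inpatient_log
#' @return An [event_log()].
#' @export
extract_er_log <- function(dataset, spec) {
  stopifnot(spec$process_type == "er")
  vids <- select_cohort(dataset, spec)
  v <- dataset$visit_occurrence |> filter(.data$visit_occurrence_id %in% vids)
  ev <- scoped_visit_events(dataset, spec, vids)
  labels <- journey_table_labels()
  interior <- tibble(
    case_id = as.character(ev$visit_occurrence_id),
    event_id = event_ids(ev$source_table, ev$event_row_id),
    activity = if (spec$er_activity == "table") unname(labels[ev$source_table])
               else resolve_concept(dataset, ev$concept_id, style = "id_name"),
    timestamp = ev$event_datetime,
    originator = ifelse(is.na(ev$provider_id), "", paste0("O", ev$provider_id)),
    source_table = ev$source_table,
    event_row_id = ev$event_row_id,
    concept_id = ev$concept_id,
    date_only = ev$date_only)
  if (any(is.na(v$admitting_source_concept_id)) ||
      any(is.na(v$discharge_to_concept_id))) {
    warn("ER visit(s) lack admitting-source or discharge concepts")
  }
  starts <- tibble(
    case_id = as.character(v$visit_occurrence_id),
    event_id = paste0("visit_", v$visit_occurrence_id, "_admit"),
    activity = er_admission_label(dataset, v$admitting_source_concept_id),
    timestamp = v$visit_start_datetime,
    originator = "",
    source_table = "visit_occurrence",
    event_row_id = v$visit_occurrence_id,
    concept_id = v$admitting_source_concept_id,
    date_only = FALSE)
  ends <- starts |>
    mutate(event_id = paste0("visit_", v$visit_occurrence_id, "_discharge"),
           activity = er_discharge_label(dataset, v$discharge_to_concept_id),
           timestamp = v$visit_end_datetime,
           concept_id = v$discharge_to_concept_id)
  cases <- tibble(
    case_id = as.character(v$visit_occurrence_id),
    person_id = v$person_id,
    los_hours = compute_los(v, "hours"),
    admitting_source = er_admission_label(dataset, v$admitting_source_concept_id),
    discharge_to = er_discharge_label(dataset, v$discharge_to_concept_id)) |>
    bind_cols(person_case_attrs(dataset, v)[c("sex", "age")])
  event_log(bind_rows(starts, interior, ends), cases = cases,
            process_type = "er")
}

#' Extract a patient-journey event log
#'
#' Case id is the person; qualifying patients are those with a cohort visit
#' starting in the period, and all their visits inside `journey_window` are
#' kept. At visit level each visit becomes one event labelled by visit type;
#' at descendant level the visit's scoped rows are labelled
#' `<Type>_<k>_<Label>` with `k` the per-type chronological visit index, and
#' duplicate (label, calendar date) events collapse to the first occurrence.
#'
#' @inheritParams extract_inpatient_log
#' @param visit_labels Named map from visit concept id to visit-type label.
#' @return An [event_log()].
#' @export
extract_patient_journey_log <- function(dataset, spec,
                                        visit_labels = visit_type_labels()) {
  stopifnot(spec$process_type == "patient_journey")
  pids <- select_cohort(dataset, spec)
  v <- dataset$visit_occurrence |>
    filter(.data$person_id %in% pids,
           .data$visit_start_datetime >= spec$journey_window[1],
           .data$visit_start_datetime < spec$journey_window[2]) |>
    arrange(.data$person_id, .data$visit_start_datetime)
  if (nrow(v) == 0) {
    warn("no visits found inside the journey window")
  }
  if (!"provider_id" %in% names(v)) v$provider_id <- NA_integer_
  abbrevs <- visit_type_abbrev()
  v <- v |>
    group_by(.data$person_id, .data$visit_concept_id) |>
    mutate(type_index = row_number()) |>
    ungroup() |>
    mutate(
      type_label = unname(visit_labels[as.character(.data$visit_concept_id)]),
      type_abbrev = unname(abbrevs[as.character(.data$visit_concept_id)]))
  if (any(is.na(v$type_label))) {
    warn(paste0("visit concept id(s) without a journey label: ",
                paste(unique(v$visit_concept_id[is.na(v$type_label)]), collapse = ", ")))
    v$type_label[is.na(v$type_label)] <-
      paste0("Visit ", v$visit_concept_id[is.na(v$type_label)])
    v$type_abbrev[is.na(v$type_abbrev)] <-
      paste0("V", v$visit_concept_id[is.na(v$type_abbrev)])
  }
  cases <- dataset$person |>
    filter(.data$person_id %in% pids) |>
    mutate(case_id = as.character(.data$person_id),
           sex = resolve_concept(dataset, .data$gender_concept_id,
                                 style = "id_name")) |>
    select("case_id", "person_id", "sex", "year_of_birth")
  if (spec$journey_level == "visit") {
    events <- tibble(
      case_id = as.character(v$person_id),
      event_id = paste0("visit_", v$visit_occurrence_id),
      activity = v$type_label,
      timestamp = v$visit_start_datetime,
      originator = ifelse(is.na(v$provider_id), "", paste0("O", v$provider_id)),
      source_table = "visit_occurrence",
      event_row_id = v$visit_occurrence_id,
      concept_id = v$visit_concept_id,
      date_only = FALSE,
      visit_index = v$type_index)
    return(event_log(events, cases = cases, process_type = "patient_journey"))
  }
  ev <- cdm_events(dataset, tables = spec$scope) |>
    filter(.data$visit_occurrence_id %in% v$visit_occurrence_id)
  vkey <- v |> select("visit_occurrence_id", "type_abbrev", "type_index")
  labels <- journey_table_labels()
  ev <- ev |>
    left_join(vkey, by = "visit_occurrence_id") |>
    mutate(
      label = if (spec$journey_activity == "table") unname(labels[.data$source_table])
              else resolve_concept(dataset, .data$concept_id, style = "id_name"),
      activity = paste0(.data$type_abbrev, "_", .data$type_index, "_", .data$label))
  events <- tibble(
    case_id = as.character(ev$person_id),
    event_id = event_ids(ev$source_table, ev$event_row_id),
    activity = ev$activity,
    timestamp = ev$event_datetime,
    originator = ifelse(is.na(ev$provider_id), "", paste0("O", ev$provider_id)),
    source_table = ev$source_table,
    event_row_id = ev$event_row_id,
    concept_id = ev$concept_id,
    date_only = ev$date_only,
    visit_index = ev$type_index)
  # first occurrence per (activity label, calendar date) within a case
  events <- sort_log_events(events) |>
    mutate(.day = as.Date(.data$timestamp, tz = "UTC")) |>
    distinct(.data$case_id, .data$activity, .data$.day, .keep_all = TRUE) |>
    select(-".day")
  if (isTRUE(spec$journey_markers)) {
    markers <- bind_rows(
      tibble(case_id = as.character(v$person_id),
             event_id = paste0("visit_", v$visit_occurrence_id, "_start"),
             activity = paste0(v$type_abbrev, "_", v$type_index, "_Start"),
             timestamp = v$visit_start_datetime,
             originator = "", source_table = "visit_occurrence",
             event_row_id = v$visit_occurrence_id,
             concept_id = v$visit_concept_id, date_only = FALSE,
             visit_index = v$type_index),
      tibble(case_id = as.character(v$person_id),
             event_id = paste0("visit_", v$visit_occurrence_id, "_end"),
             activity = paste0(v$type_abbrev, "_", v$type_index, "_End"),
             timestamp = v$visit_end_datetime,
             originator = "", source_table = "visit_occurrence",
             event_row_id = v$visit_occurrence_id,
             concept_id = v$visit_concept_id, date_only = FALSE,
             visit_index = v$type_index))
    events <- bind_rows(events, markers)
  }
  event_log(events, cases = cases, process_type = "patient_journey")
}

#' Extract an event log for any process type
#'
#' Dispatches on `spec$process_type`.
#'
#' @inheritParams extract_inpatient_log
#' @return An [event_log()].
#' @export
extract_log <- function(dataset, spec) {
  switch(spec$process_type,
    inpatient = extract_inpatient_log(dataset, spec),
    outpatient = extract_outpatient_log(dataset, spec),
    er = extract_er_log(dataset, spec),
    patient_journey = extract_patient_journey_log(dataset, spec))
}
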