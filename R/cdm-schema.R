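# Minimal OMOP CDM (v5.3+) schema used throughout the package.
#
# Only the columns the extractors need are mandatory; extra columns found in a
# CDM dump pass through load/write untouched. The cost and note tables are
# simplified to a (concept_id, datetime) shape so they can act as activity
# sources like the five clinical event tables.

# Activity-bearing event tables: canonical id / concept / datetime columns.
cdm_event_schema <- function() {
  tibble::tribble(
    ~table,                 ~id_col,                   ~concept_col,            ~datetime_col,                 ~rank,
    "condition_occurrence", "condition_occurrence_id", "condition_concept_id",  "condition_start_datetime",    1L,
    "procedure_occurrence", "procedure_occurrence_id", "procedure_concept_id",  "procedure_datetime",          2L,
    "measurement",          "measurement_id",          "measurement_concept_id","measurement_datetime",        3L,
    "drug_exposure",        "drug_exposure_id",        "drug_concept_id",       "drug_exposure_start_datetime",4L,
    "device_exposure",      "device_exposure_id",      "device_concept_id",     "device_exposure_start_datetime",5L,
    "observation",          "observation_id",          "observation_concept_id","observation_datetime",        6L,
    "cost",                 "cost_id",                 "cost_concept_id",       "cost_datetime",               7L,
    "note",                 "note_id",                 "note_concept_id",       "note_datetime",               8L
  )
}

cdm_event_tables <- function() cdm_event_schema()$table

# Tie-break rank for equal timestamps within a case.
source_table_rank <- function(tables) {
  sch <- cdm_event_schema()
  r <- sch$rank[match(tables, sch$table)]
  # visit-derived boundary events sort outside the clinical tables
  r[tables == "visit_occurrence"] <- 0L
  r[is.na(r)] <- 99L
  r
}

cdm_all_tables <- function(include_note = TRUE) {
  tabs <- c("person", "visit_occurrence", cdm_event_tables(),
            "provider", "care_site", "concept", "concept_ancestor")
  if (!include_note) tabs <- setdiff(tabs, "note")
  tabs
}

cdm_mandatory_tables <- function() c("person", "visit_occurrence", "concept")

# Required columns per table (the extraction surface).
cdm_required_columns <- function(table) {
  sch <- cdm_event_schema()
  if (table %in% sch$table) {
    row <- sch[sch$table == table, ]
    return(c(row$id_col, "visit_occurrence_id", "person_id",
             row$concept_col, row$datetime_col))
  }
  switch(table,
    person = c("person_id", "gender_concept_id", "year_of_birth"),
    visit_occurrence = c("visit_occurrence_id", "person_id", "visit_concept_id",
                         "visit_start_datetime", "visit_end_datetime"),
    provider = c("provider_id"),
    care_site = c("care_site_id"),
    concept = c("concept_id", "concept_name", "domain_id"),
    concept_ancestor = c("ancestor_concept_id", "descendant_concept_id"),
    abort(paste0("unknown CDM table: ", table))
  )
}

# Columns holding timestamps, per table.
cdm_datetime_columns <- function(table) {
  sch <- cdm_event_schema()
  if (table %in% sch$table) return(sch$datetime_col[sch$table == table])
  if (table == "visit_occurrence") {
    return(c("visit_start_datetime", "visit_end_datetime"))
  }
  character(0)
}

#' Built-in OMOP concept vocabulary
#'
#' A small concept table covering the standard visit, gender, admission-source
#' and discharge concepts the extractors rely on, plus a handful of clinical
#' order concepts commonly seen around a laparoscopic hysterectomy admission.
#' The synthetic generators extend it with generated order concepts. Names of
#' visit-source concepts follow the admission-side rendering ("Visit from
#' home"); the checkup visit concept 9205 is a synthetic stand-in, as OMOP has
#' no single canonical checkup visit concept.
#'
#' @return A tibble with columns `concept_id`, `concept_name`, `domain_id`.
#' @export
#' @examples
#' base_concepts()
base_concepts <- function() {
  tibble::tribble(
    ~concept_id, ~concept_name, ~domain_id,
    9201L,     "Inpatient visit",                                "Visit",
    9202L,     "Outpatient visit",                               "Visit",
    9203L,     "Emergency Room visit",                           "Visit",
    262L,      "Emergency Room and Inpatient visit",             "Visit",
    32036L,    "Laboratory visit",                               "Visit",
    9205L,     "Checkup visit",                                  "Visit",
    8532L,     "Female",                                         "Gender",
    8507L,     "Male",                                           "Gender",
    8536L,     "Visit from home",                                "Visit",
    44790567L, "Patient transfer from hospital to hospital",     "Visit",
    8716L,     "Visit from independent clinic",                  "Visit",
    8717L,     "Visit from inpatient hospital",                  "Visit",
    8756L,     "Transfer from outpatients",                      "Visit",
    40318361L, "Patient registration",                           "Observation",
    1154186L,  "fentanyl 0.1 MG",                                "Drug",
    19086213L, "midazolam 5 MG/ML",                              "Drug",
    35605373L, "remifentanil 1 MG",                              "Drug",
    35605994L, "cefotetan 1000 MG",                              "Drug",
    925043L,   "bisacodyl 5 MG",                                 "Drug",
    19077241L, "famotidine 20 MG Oral Tablet",                   "Drug",
    19086516L, "aceclofenac 100 MG",                             "Drug",
    3012608L,  "segmented neutrophils/100 leukocytes in blood by automated count", "Measurement",
    3013869L,  "basophils/100 leukocytes in blood by automated count",             "Measurement"
  )
}

er_source_concepts <- function() c(8536L, 44790567L, 8716L, 8717L, 8756L)

visit_type_labels <- function() {
  c("9201" = "Inpatient visit",
    "9202" = "Outpatient visit",
    "9203" = "Emergency room visit",
    "32036" = "Laboratory visit",
    "9205" = "Checkup visit",
    "262" = "Emergency room and inpatient visit")
}

visit_type_abbrev <- function() {
  c("9201" = "In", "9202" = "Out", "9203" = "ER",
    "32036" = "Lab", "9205" = "Check", "262" = "ERIn")
}

# Short per-table activity labels used at descendant level of patient journeys.
journey_table_labels <- function() {
  c(condition_occurrence = "Condition", procedure_occurrence = "Procedure",
    measurement = "Measurement", drug_exposure = "Drug",
    device_exposure = "Device", observation = "Observation",
    cost = "Payment", note = "Note")
}

# Table-level activity mapping for outpatient logs.
outpatient_table_labels <- function() {
  c(condition_occurrence = "Consultation",
    visit_occurrence = "Consultation",
    measurement = "Physical examination & Lab test",
    drug_exposure = "Drug",
    procedure_occurrence = "Surgery & Radiology test",
    cost = "Payment",
    observation = "Survey",
    device_exposure = "Device",
    note = "Note")
}
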