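#' Assemble an OMOP CDM dataset from tables
#'
#' A `cdm_dataset` is a named list of tibbles, one per CDM table, carrying the
#' minimal column set the extractors need (extra columns are preserved).
#' Missing optional tables are filled with empty relations; the activity tables
#' gain a logical `date_only` column marking rows whose source recorded only a
#' calendar date.
#'
#' @param ... Named tibbles, e.g. `person = ...`, `visit_occurrence = ...`.
#'   Alternatively a single named list.
#' @param concepts Concept vocabulary tibble; defaults to [base_concepts()]
#'   when no `concept` table is supplied.
#' @return A `cdm_dataset` object.
#' @export
#' @examples
#' cdm <- cdm_dataset(
#'   person = tibble::tibble(person_id = 1L, gender_concept_id = 8532L,
#'                           year_of_birth = 1981L)
#' )
#' names(cdm)
cdm_dataset <- function(..., concepts = NULL) {
  tabs <- list(...)
  if (length(tabs) == 1L && is.null(names(tabs)) ||
      (length(tabs) == 1L && is.list(tabs[[1]]) && !is.data.frame(tabs[[1]]))) {
    tabs <- tabs[[1]]
  }
  unknown <- setdiff(names(tabs), cdm_all_tables())
  if (length(unknown) > 0) {
    abort(paste0("unknown CDM table(s): ", paste(unknown, collapse = ", ")))
  }
  keep_note <- "note" %in% names(tabs)
  out <- list()
  for (tb in cdm_all_tables(include_note = keep_note)) {
    x <- tabs[[tb]]
    if (is.null(x)) x <- empty_cdm_table(tb)
    out[[tb]] <- normalize_cdm_table(as_tibble(x), tb)
  }
  if (!is.null(concepts)) {
    out$concept <- normalize_cdm_table(as_tibble(concepts), "concept")
  } else if (nrow(out$concept) == 0L) {
    out$concept <- base_concepts()
  }
  structure(out, class = c("cdm_dataset", "list"))
}

#' @export
print.cdm_dataset <- function(x, ...) {
  cat("<cdm_dataset> with", length(x), "tables\n")
  for (tb in names(x)) cat(sprintf("  %-22s %6d rows\n", tb, nrow(x[[tb]])))
  invisible(x)
}

empty_cdm_table <- function(table) {
  cols <- cdm_required_columns(table)
  proto <- function(col) {
    if (grepl("_datetime$", col)) return(as.POSIXct(character(0), tz = "UTC"))
    if (col %in% c("concept_name", "domain_id")) return(character(0))
    integer(0)
  }
  out <- as_tibble(setNames(lapply(cols, proto), cols))
  if (table %in% cdm_event_tables()) {
    out$date_only <- logical(0)
    out$provider_id <- integer(0)
  }
  if (table == "visit_occurrence") {
    out$provider_id <- integer(0)
    out$care_site_id <- integer(0)
    out$admitting_source_concept_id <- integer(0)
    out$discharge_to_concept_id <- integer(0)
  }
  if (table == "provider") out$provider_name <- character(0)
  if (table == "care_site") out$care_site_name <- character(0)
  out
}

normalize_cdm_table <- function(x, table) {
  req <- cdm_required_columns(table)
  missing <- setdiff(req, names(x))
  if (length(missing) > 0) {
    abort(paste0("table '", table, "' lacks required column(s): ",
                 paste(missing, collapse = ", ")))
  }
  for (col in cdm_datetime_columns(table)) {
    if (!inherits(x[[col]], "POSIXct")) {
      x[[col]] <- parse_cdm_datetime(as.character(x[[col]]))$datetime
    }
    attr(x[[col]], "tzone") <- "UTC"
  }
  int_cols <- setdiff(intersect(names(x), c(
    req[grepl("_id$", req)], "provider_id", "care_site_id",
    "admitting_source_concept_id", "discharge_to_concept_id", "year_of_birth")),
    "domain_id")
  for (col in int_cols) x[[col]] <- as.integer(x[[col]])
  if (table %in% cdm_event_tables()) {
    if (!"date_only" %in% names(x)) x$date_only <- rep(FALSE, nrow(x))
    x$date_only <- as.logical(x$date_only)
    if (!"provider_id" %in% names(x)) x$provider_id <- rep(NA_integer_, nrow(x))
  }
  if (table == "visit_occurrence") {
    for (col in c("provider_id", "care_site_id",
                  "admitting_source_concept_id", "discharge_to_concept_id")) {
      if (!col %in% names(x)) x[[col]] <- rep(NA_integer_, nrow(x))
    }
  }
  x
}

# Parse CDM datetime text. A bare calendar date (no time component in the
# source text) parses to midnight with date_only = TRUE; midnight written with
# an explicit time component stays date_only = FALSE.
parse_cdm_datetime <- function(txt) {
  txt <- trimws(txt)
  txt[txt == ""] <- NA_character_
  date_only <- !is.na(txt) & !grepl("[T ]", txt)
  norm <- ifelse(date_only, paste0(txt, " 00:00:00"), sub("T", " ", txt))
  dt <- as.POSIXct(norm, tz = "UTC", format = "%Y-%m-%d %H:%M:%S")
  # allow minute-resolution sources
  retry <- is.na(dt) & !is.na(norm)
  dt[retry] <- as.POSIXct(norm[retry], tz = "UTC", format = "%Y-%m-%d %H:%M")
  list(datetime = dt, date_only = date_only, failed = is.na(dt) & !is.na(txt))
}

format_cdm_datetime <- function(x) {
  format(x, format = "%Y-%m-%d %H:%M:%S", tz = "UTC")
}

#' Load an OMOP CDM table set from delimited files
#'
#' Reads one CSV per table (`<table>.csv`) from a directory. Timestamp columns
#' carrying only a calendar date are parsed to midnight and flagged
#' `date_only = TRUE`. Rows whose timestamps cannot be parsed are skipped and
#' collected into a load report (attribute `"load_report"`).
#'
#' @param source Directory containing per-table CSV files.
#' @param table_names Tables to read; defaults to the full minimal table set.
#'   Missing non-mandatory tables load as empty relations.
#' @return A [cdm_dataset()].
#' @export
load_cdm <- function(source, table_names = cdm_all_tables()) {
  if (!dir.exists(source)) abort(paste0("CDM source directory not found: ", source))
  report <- list()
  tabs <- list()
  for (tb in table_names) {
    path <- file.path(source, paste0(tb, ".csv"))
    if (!file.exists(path)) {
      if (tb %in% cdm_mandatory_tables()) {
        abort(paste0("mandatory CDM table missing: ", tb, " (", path, ")"))
      }
      if (tb != "note") tabs[[tb]] <- empty_cdm_table(tb)
      next
    }
    raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_guess()),
                           comment = "#", progress = FALSE, show_col_types = FALSE)
    dt_cols <- cdm_datetime_columns(tb)
    if (nrow(raw) > 0 && length(dt_cols) > 0) {
      raw2 <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                              comment = "#", progress = FALSE, show_col_types = FALSE)
      bad <- rep(FALSE, nrow(raw))
      has_file_flag <- "date_only" %in% names(raw)
      for (col in intersect(dt_cols, names(raw))) {
        p <- parse_cdm_datetime(raw2[[col]])
        raw[[col]] <- p$datetime
        bad <- bad | p$failed
        if (tb %in% cdm_event_tables() && !has_file_flag) raw$date_only <- p$date_only
      }
      if (any(bad)) {
        report[[tb]] <- tibble(table = tb, row = which(bad),
                               message = "unparseable timestamp; row skipped")
        raw <- raw[!bad, , drop = FALSE]
      }
    }
    tabs[[tb]] <- raw
  }
  out <- cdm_dataset(tabs)
  attr(out, "load_report") <- list_rbind(report)
  out
}

#' Write a CDM dataset to per-table CSV files
#'
#' One RFC-4180 CSV per table, named `<table>.csv`, with exact CDM column
#' names. Timestamps are written at second resolution;
#' `load_cdm(write_cdm(d))` reproduces `d` field by field.
#'
#' @param dataset A [cdm_dataset()].
#' @param target Output directory (created if needed).
#' @param provenance Optional named character vector written as `#`-prefixed
#'   header comment lines in every file.
#' @return Invisibly, the paths written.
#' @export
write_cdm <- function(dataset, target, provenance = NULL) {
  stopifnot(inherits(dataset, "cdm_dataset"))
  dir.create(target, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (tb in names(dataset)) {
    x <- dataset[[tb]]
    for (col in cdm_datetime_columns(tb)) {
      x[[col]] <- format_cdm_datetime(x[[col]])
    }
    path <- file.path(target, paste0(tb, ".csv"))
    if (!is.null(provenance)) {
      writeLines(paste0("# ", names(provenance), ": ", provenance), path)
      readr::write_csv(x, path, append = TRUE, col_names = TRUE)
    } else {
      readr::write_csv(x, path)
    }
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' Validate referential and temporal integrity of a CDM dataset
#'
#' Checks: visits with `end < start` (`visit_window`), dangling foreign keys
#' from visits and events (`dangling_fk`), events dated outside their visit
#' window (`event_within_visit`), and visit concept ids absent from the
#' vocabulary (`unknown_visit_concept`). Findings are report rows, never
#' errors; an empty report means the dataset passes.
#'
#' @param dataset A [cdm_dataset()].
#' @return A tibble of violations (class `cdm_validation`) with columns
#'   `rule`, `table`, `row_id`, `message`.
#' @export
validate_cdm <- function(dataset) {
  stopifnot(inherits(dataset, "cdm_dataset"))
  v <- dataset$visit_occurrence
  out <- list()
  bad <- which(v$visit_end_datetime < v$visit_start_datetime)
  if (length(bad) > 0) {
    out[[length(out) + 1L]] <- tibble(
      rule = "visit_window", table = "visit_occurrence",
      row_id = v$visit_occurrence_id[bad],
      message = "visit_end_datetime earlier than visit_start_datetime")
  }
  dangling <- which(!v$person_id %in% dataset$person$person_id)
  if (length(dangling) > 0) {
    out[[length(out) + 1L]] <- tibble(
      rule = "dangling_fk", table = "visit_occurrence",
      row_id = v$visit_occurrence_id[dangling],
      message = "person_id not found in person table")
  }
  unknown <- which(!v$visit_concept_id %in% dataset$concept$concept_id)
  if (length(unknown) > 0) {
    out[[length(out) + 1L]] <- tibble(
      rule = "unknown_visit_concept", table = "visit_occurrence",
      row_id = v$visit_occurrence_id[unknown],
      message = paste0("visit_concept_id ", v$visit_concept_id[unknown],
                       " absent from vocabulary"))
  }
  vkey <- v |>
    select("visit_occurrence_id",
           vstart = "visit_start_datetime", vend = "visit_end_datetime")
  for (tb in intersect(cdm_event_tables(), names(dataset))) {
    ev <- dataset[[tb]]
    if (nrow(ev) == 0) next
    sch <- cdm_event_schema()
    row <- sch[sch$table == tb, ]
    dangle <- which(!ev$visit_occurrence_id %in% v$visit_occurrence_id)
    if (length(dangle) > 0) {
      out[[length(out) + 1L]] <- tibble(
        rule = "dangling_fk", table = tb, row_id = ev[[row$id_col]][dangle],
        message = "visit_occurrence_id not found in visit table")
    }
    joined <- ev |>
      mutate(.row_id = .data[[row$id_col]],
             .dt = .data[[row$datetime_col]]) |>
      left_join(vkey, by = "visit_occurrence_id") |>
      filter(!is.na(.data$vstart))
    outside <- joined |>
      filter(as.Date(.data$.dt) < as.Date(.data$vstart) |
               as.Date(.data$.dt) > as.Date(.data$vend))
    if (nrow(outside) > 0) {
      out[[length(out) + 1L]] <- tibble(
        rule = "event_within_visit", table = tb, row_id = outside$.row_id,
        message = "event date outside visit window")
    }
  }
  rep <- if (length(out) == 0) {
    tibble(rule = character(0), table = character(0),
           row_id = integer(0), message = character(0))
  } else {
    list_rbind(out)
  }
  class(rep) <- c("cdm_validation", class(rep))
  rep
}

#' @export
print.cdm_validation <- function(x, ...) {
  if (nrow(x) == 0) {
    cat("<cdm_validation> no violations\n")
  } else {
    cat("<cdm_validation>", nrow(x), "violation(s)\n")
    print(dplyr::count(as_tibble(x), .data$rule, .data$table))
  }
  invisible(x)
}

#' Resolve concept ids to display names
#'
#' @param dataset A [cdm_dataset()] whose `concept` table is the vocabulary.
#' @param concept_id Integer vector of concept ids.
#' @param style `"name"` returns the bare concept name; `"id_name"` the
#'   `"<id> (<name>)"` rendering used for event-log activities.
#' @return Character vector. Unknown ids render as `"<id> (unknown)"` with a
#'   warning.
#' @export
#' @examples
#' cdm <- cdm_dataset()
#' resolve_concept(cdm, 9202L)
#' resolve_concept(cdm, 8532L, style = "id_name")
resolve_concept <- function(dataset, concept_id, style = c("name", "id_name")) {
  style <- match.arg(style)
  voc <- dataset$concept
  nm <- voc$concept_name[match(concept_id, voc$concept_id)]
  if (anyNA(nm) && any(!is.na(concept_id) & is.na(nm))) {
    miss <- unique(concept_id[is.na(nm) & !is.na(concept_id)])
    warn(paste0("unknown concept id(s): ", paste(miss, collapse = ", ")))
    nm[is.na(nm)] <- "unknown"
  }
  if (style == "name") nm else paste0(concept_id, " (", nm, ")")
}

#' Descendants of a concept via the concept_ancestor table
#'
#' Returns every descendant concept id stored for `ancestor_id`, always
#' including the ancestor itself. When the id is absent from the ancestor
#' table the singleton set is returned with a warning.
#'
#' @param dataset A [cdm_dataset()].
#' @param ancestor_id Single concept id.
#' @return Integer vector of concept ids.
#' @export
concept_descendants <- function(dataset, ancestor_id) {
  ca <- dataset$concept_ancestor
  hits <- ca$descendant_concept_id[ca$ancestor_concept_id == ancestor_id]
  if (length(hits) == 0) {
    warn(paste0("concept ", ancestor_id, " absent from concept_ancestor; ",
                "returning the concept itself"))
  }
  sort(unique(c(as.integer(ancestor_id), hits)))
}

# Normalized long view over the activity-bearing tables:
# source_table, event_row_id, visit_occurrence_id, person_id, concept_id,
# event_datetime, date_only, provider_id (+ any requested feature columns).
cdm_events <- function(dataset, tables = cdm_event_tables()) {
  sch <- cdm_event_schema()
  rows <- list()
  for (tb in intersect(tables, names(dataset))) {
    x <- dataset[[tb]]
    if (nrow(x) == 0) next
    row <- sch[sch$table == tb, ]
    rows[[tb]] <- tibble(
      source_table = tb,
      event_row_id = as.integer(x[[row$id_col]]),
      visit_occurrence_id = x$visit_occurrence_id,
      person_id = x$person_id,
      concept_id = as.integer(x[[row$concept_col]]),
      event_datetime = x[[row$datetime_col]],
      date_only = if ("date_only" %in% names(x)) x$date_only else FALSE,
      provider_id = if ("provider_id" %in% names(x)) x$provider_id
                    else NA_integer_
    )
  }
  if (length(rows) == 0) {
    return(tibble(source_table = character(0), event_row_id = integer(0),
                  visit_occurrence_id = integer(0), person_id = integer(0),
                  concept_id = integer(0),
                  event_datetime = as.POSIXct(character(0), tz = "UTC"),
                  date_only = logical(0), provider_id = integer(0)))
  }
  list_rbind(rows)
}
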