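#' Construct an event log
#'
#' An `event_log` is a tibble of events — one row per event with at least
#' `case_id`, `event_id`, `activity`, `timestamp` — sorted within case by
#' timestamp (ties broken by source-table rank then row id), carrying a
#' per-case attribute table (`log_cases()`) and the process type as
#' attributes.
#'
#' @param events Tibble with columns `case_id`, `event_id`, `activity`,
#'   `timestamp` and optionally `originator`, `source_table`, `event_row_id`,
#'   `concept_id`, `date_only` plus arbitrary attribute columns.
#' @param cases Tibble of case attributes keyed by `case_id`; defaults to the
#'   distinct case ids.
#' @param process_type Label of the process the log describes.
#' @return An `event_log`.
#' @export
#' @examples
#' log <- event_log(tibble::tibble(
#'   case_id = "c1", event_id = c("e1", "e2"), activity = c("a", "b"),
#'   timestamp = as.POSIXct(c("2021-08-01 09:00:00", "2021-08-01 10:00:00"),
#'                          tz = "UTC")))
#' glance(log)
event_log <- function(events, cases = NULL, process_type = "generic") {
  events <- as_tibble(events)
  req <- c("case_id", "event_id", "activity", "timestamp")
  missing <- setdiff(req, names(events))
  if (length(missing) > 0) {
    abort(paste0("event log lacks column(s): ", paste(missing, collapse = ", ")))
  }
  events$case_id <- as.character(events$case_id)
  events$event_id <- as.character(events$event_id)
  if (!"originator" %in% names(events)) events$originator <- ""
  events$originator[is.na(events$originator)] <- ""
  if (!"source_table" %in% names(events)) events$source_table <- NA_character_
  if (!"event_row_id" %in% names(events)) events$event_row_id <- NA_integer_
  if (!"concept_id" %in% names(events)) events$concept_id <- NA_integer_
  if (!"date_only" %in% names(events)) events$date_only <- FALSE
  attr(events$timestamp, "tzone") <- "UTC"
  events <- sort_log_events(events)
  if (is.null(cases)) {
    cases <- tibble(case_id = unique(events$case_id))
  } else {
    cases <- as_tibble(cases)
    cases$case_id <- as.character(cases$case_id)
  }
  if (anyDuplicated(cases$case_id)) abort("case_id must be unique per log")
  cases <- cases[order(cases$case_id), , drop = FALSE]
  structure(events,
            cases = cases,
            process_type = process_type,
            class = c("event_log", class(tibble())))
}

sort_log_events <- function(events) {
  ord <- order(events$case_id, events$timestamp,
               source_table_rank(events$source_table), events$event_row_id)
  events[ord, , drop = FALSE]
}

#' Case attribute table of an event log
#' @param log An [event_log()].
#' @return Tibble of case attributes, one row per case.
#' @export
log_cases <- function(log) {
  stopifnot(inherits(log, "event_log"))
  attr(log, "cases")
}

#' Process type of an event log
#' @param log An [event_log()].
#' @return Character scalar.
#' @export
log_process_type <- function(log) attr(log, "process_type") %||% "generic"

#' @export
print.event_log <- function(x, ...) {
  cat("<event_log>", log_process_type(x), "process:",
      nrow(log_cases(x)), "cases,", nrow(x), "events,",
      dplyr::n_distinct(x$activity), "activities\n")
  NextMethod()
}

#' @rdname event_log
#' @param x An `event_log`.
#' @param ... Unused.
#' @export
tidy.event_log <- function(x, ...) {
  out <- as_tibble(x)
  attr(out, "cases") <- NULL
  attr(out, "process_type") <- NULL
  out
}

#' @rdname event_log
#' @export
glance.event_log <- function(x, ...) {
  tibble(
    process_type = log_process_type(x),
    n_cases = nrow(log_cases(x)),
    n_events = nrow(x),
    n_activities = dplyr::n_distinct(x$activity),
    first_event = suppressWarnings(min(x$timestamp)),
    last_event = suppressWarnings(max(x$timestamp))
  )
}

#' Write an event log to CSV or XES
#'
#' The CSV dialect places the event fields first (`case_id`, `event_id`,
#' `activity`, `timestamp`, `originator`, `source_table`, ...) followed by the
#' case attributes repeated per row under a `case_` prefix; a header comment
#' records the process type. XES uses the standard trace/event elements with
#' `concept:name`, `time:timestamp` and `org:resource` keys.
#' `read_log(write_log(x))` reproduces `x` up to attribute column order.
#'
#' @param log An [event_log()].
#' @param target Output file path.
#' @param format `"csv"` or `"xes"`.
#' @param provenance Optional named character vector added to the CSV comment
#'   header (ignored for XES).
#' @return Invisibly, `target`.
#' @export
write_log <- function(log, target, format = c("csv", "xes"), provenance = NULL) {
  format <- match.arg(format)
  stopifnot(inherits(log, "event_log"))
  if (format == "csv") write_log_csv(log, target, provenance) else write_log_xes(log, target)
  invisible(target)
}

write_log_csv <- function(log, target, provenance = NULL) {
  events <- tidy(log)
  events$timestamp <- format_cdm_datetime(events$timestamp)
  cases <- log_cases(log)
  extra <- cases[, setdiff(names(cases), "case_id"), drop = FALSE]
  if (ncol(extra) > 0) {
    names(extra) <- paste0("case_", names(extra))
    extra$case_id <- cases$case_id
    for (col in names(extra)) {
      if (inherits(extra[[col]], "POSIXct")) extra[[col]] <- format_cdm_datetime(extra[[col]])
    }
    events <- left_join(events, extra, by = "case_id")
  }
  hdr <- c(process_type = log_process_type(log), provenance)
  writeLines(paste0("# ", names(hdr), ": ", hdr), target)
  readr::write_csv(events, target, append = TRUE, col_names = TRUE)
}

read_log_csv <- function(source) {
  head_lines <- readLines(source, n = 20L)
  ptype <- sub("^# process_type: ", "",
               grep("^# process_type: ", head_lines, value = TRUE)[1])
  if (is.na(ptype)) ptype <- "generic"
  x <- readr::read_csv(source, comment = "#", progress = FALSE,
                       show_col_types = FALSE)
  x$timestamp <- as.POSIXct(as.character(x$timestamp), tz = "UTC")
  x$case_id <- as.character(x$case_id)
  case_cols <- grep("^case_(?!id$)", names(x), value = TRUE, perl = TRUE)
  cases <- x |>
    select("case_id", all_of(case_cols)) |>
    distinct(.data$case_id, .keep_all = TRUE)
  names(cases) <- sub("^case_(?!id$)", "", names(cases), perl = TRUE)
  events <- x[, setdiff(names(x), case_cols), drop = FALSE]
  if ("event_row_id" %in% names(events)) events$event_row_id <- as.integer(events$event_row_id)
  if ("concept_id" %in% names(events)) events$concept_id <- as.integer(events$concept_id)
  if ("originator" %in% names(events)) events$originator <- as.character(events$originator)
  event_log(events, cases = cases, process_type = ptype)
}

xes_attr_node <- function(parent, value, key) {
  if (inherits(value, "POSIXct")) {
    xml2::xml_add_child(parent, "date", key = key,
                        value = format(value, "%Y-%m-%dT%H:%M:%S+00:00", tz = "UTC"))
  } else if (is.logical(value)) {
    xml2::xml_add_child(parent, "boolean", key = key,
                        value = ifelse(value, "true", "false"))
  } else if (is.integer(value)) {
    xml2::xml_add_child(parent, "int", key = key, value = as.character(value))
  } else if (is.numeric(value)) {
    xml2::xml_add_child(parent, "float", key = key, value = as.character(value))
  } else {
    xml2::xml_add_child(parent, "string", key = key, value = as.character(value))
  }
  invisible(parent)
}

write_log_xes <- function(log, target) {
  doc <- xml2::xml_new_root("log", "xes.version" = "2.0",
                            "xes.features" = "nested-attributes")
  xes_attr_node(doc, log_process_type(log), "omopflow:process_type")
  events <- tidy(log)
  cases <- log_cases(log)
  std <- c("case_id", "event_id", "activity", "timestamp", "originator")
  extra_cols <- setdiff(names(events), std)
  for (cid in cases$case_id) {
    tr <- xml2::xml_add_child(doc, "trace")
    xes_attr_node(tr, cid, "concept:name")
    crow <- cases[cases$case_id == cid, , drop = FALSE]
    for (col in setdiff(names(cases), "case_id")) {
      if (!is.na(crow[[col]][1])) xes_attr_node(tr, crow[[col]][1], col)
    }
    evs <- events[events$case_id == cid, , drop = FALSE]
    for (j in seq_len(nrow(evs))) {
      e <- xml2::xml_add_child(tr, "event")
      xes_attr_node(e, evs$activity[j], "concept:name")
      xes_attr_node(e, evs$timestamp[j], "time:timestamp")
      if (nzchar(evs$originator[j])) xes_attr_node(e, evs$originator[j], "org:resource")
      xes_attr_node(e, evs$event_id[j], "omopflow:event_id")
      for (col in extra_cols) {
        if (!is.na(evs[[col]][j])) xes_attr_node(e, evs[[col]][j], col)
      }
    }
  }
  xml2::write_xml(doc, target)
}

xes_read_attrs <- function(node) {
  kids <- xml2::xml_find_all(node, "./*[not(self::event) and not(self::trace)]")
  keys <- xml2::xml_attr(kids, "key")
  vals <- xml2::xml_attr(kids, "value")
  types <- xml2::xml_name(kids)
  out <- list()
  for (i in seq_along(keys)) {
    out[[keys[i]]] <- switch(types[i],
      date = as.POSIXct(sub("T", " ", sub("\\+00:00$", "", vals[i])), tz = "UTC"),
      int = as.integer(vals[i]),
      float = as.numeric(vals[i]),
      boolean = identical(vals[i], "true"),
      vals[i])
  }
  out
}

read_log_xes <- function(source) {
  doc <- xml2::read_xml(source)
  root_attrs <- xes_read_attrs(doc)
  ptype <- root_attrs[["omopflow:process_type"]] %||% "generic"
  traces <- xml2::xml_find_all(doc, "./trace")
  case_rows <- event_rows <- vector("list", length(traces))
  for (i in seq_along(traces)) {
    tr <- traces[[i]]
    ta <- xes_read_attrs(tr)
    cid <- ta[["concept:name"]]
    ta[["concept:name"]] <- NULL
    case_rows[[i]] <- as_tibble(c(list(case_id = cid), ta))
    evs <- xml2::xml_find_all(tr, "./event")
    rows <- vector("list", length(evs))
    for (j in seq_along(evs)) {
      ea <- xes_read_attrs(evs[[j]])
      rows[[j]] <- as_tibble(c(list(
        case_id = cid,
        event_id = ea[["omopflow:event_id"]],
        activity = ea[["concept:name"]],
        timestamp = ea[["time:timestamp"]],
        originator = ea[["org:resource"]] %||% ""),
        ea[setdiff(names(ea), c("omopflow:event_id", "concept:name",
                                "time:timestamp", "org:resource"))]))
    }
    event_rows[[i]] <- list_rbind(rows)
  }
  event_log(list_rbind(event_rows), cases = list_rbind(case_rows),
            process_type = ptype)
}

#' @rdname write_log
#' @param source File to read.
#' @return `read_log()` returns an [event_log()].
#' @export
read_log <- function(source, format = c("csv", "xes")) {
  format <- match.arg(format)
  if (format == "csv") read_log_csv(source) else read_log_xes(source)
}
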