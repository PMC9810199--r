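#' Discover a directly-follows graph
#'
#' Nodes are activities with absolute event frequencies; a directed edge a->b
#' counts the consecutive occurrences of b after a within a case's
#' time-ordered trace, annotated with the mean and median inter-event duration
#' in seconds. Start/end activity frequencies complete the flow-conservation
#' identity: start(a) + inflow(a) = freq(a) = end(a) + outflow(a).
#'
#' @param log An [event_log()].
#' @return A `dfg` object (`nodes`, `edges`, `starts`, `ends` tibbles).
#' @export
#' @examples
#' log <- event_log(tibble::tibble(
#'   case_id = c("1", "1", "2", "2"), event_id = as.character(1:4),
#'   activity = c("a", "b", "a", "c"),
#'   timestamp = as.POSIXct("2021-08-01", tz = "UTC") + c(0, 60, 0, 120)))
#' discover_dfg(log)$edges
discover_dfg <- function(log) {
  stopifnot(inherits(log, "event_log"))
  events <- tidy(log)
  if (nrow(events) == 0) abort("cannot discover a model from an empty log")
  nodes <- events |> count(activity = .data$activity, name = "frequency")
  by_case <- events |>
    group_by(.data$case_id) |>
    mutate(.next = lead(.data$activity),
           .gap = as.double(lead(.data$timestamp) - .data$timestamp,
                            units = "secs")) |>
    ungroup()
  edges <- by_case |>
    filter(!is.na(.data$.next)) |>
    group_by(from = .data$activity, to = .data$.next) |>
    summarise(frequency = n(),
              mean_secs = mean(.data$.gap),
              median_secs = median(.data$.gap), .groups = "drop") |>
    arrange(desc(.data$frequency), .data$from, .data$to)
  starts <- events |>
    group_by(.data$case_id) |>
    slice(1L) |>
    ungroup() |>
    count(activity = .data$activity, name = "frequency")
  ends <- events |>
    group_by(.data$case_id) |>
    slice(n()) |>
    ungroup() |>
    count(activity = .data$activity, name = "frequency")
  structure(list(nodes = nodes, edges = edges, starts = starts, ends = ends),
            class = "dfg")
}

#' @export
print.dfg <- function(x, ...) {
  cat("<dfg>", nrow(x$nodes), "activities,", nrow(x$edges), "edges\n")
  print(head(x$edges, 10))
  invisible(x)
}

#' @rdname discover_dfg
#' @param x A `dfg`.
#' @param ... Unused.
#' @export
tidy.dfg <- function(x, ...) x$edges

#' @rdname discover_dfg
#' @export
glance.dfg <- function(x, ...) {
  tibble(n_activities = nrow(x$nodes), n_edges = nrow(x$edges),
         n_events = sum(x$nodes$frequency),
         n_cases = sum(x$starts$frequency))
}

#' @rdname discover_dfg
#' @param object A `dfg`.
#' @param stat Edge annotation: `"frequency"`, `"mean"` or `"median"` duration.
#' @export
autoplot.dfg <- function(object, stat = c("frequency", "mean", "median"), ...) {
  stat <- match.arg(stat)
  d <- object$edges |>
    mutate(value = switch(stat, frequency = .data$frequency,
                          mean = .data$mean_secs, median = .data$median_secs))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$to, y = .data$from,
                                  fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = signif(.data$value, 3)), size = 3) +
    ggplot2::labs(title = paste0("directly-follows relation (", stat, ")"),
                  x = "to", y = "from", fill = stat) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Export a directly-follows graph
#'
#' DOT for rendering with graphviz, or a JSON adjacency structure. No layout
#' is computed.
#'
#' @param dfg A `dfg`.
#' @param path Output file.
#' @param format `"dot"` or `"json"`.
#' @param stat Edge label statistic.
#' @return Invisibly, `path`.
#' @export
export_dfg <- function(dfg, path, format = c("dot", "json"),
                       stat = c("frequency", "mean", "median")) {
  format <- match.arg(format)
  stat <- match.arg(stat)
  if (format == "dot") {
    q <- function(x) paste0('"', gsub('"', '\\\\"', x), '"')
    lab <- switch(stat, frequency = dfg$edges$frequency,
                  mean = round(dfg$edges$mean_secs, 1),
                  median = round(dfg$edges$median_secs, 1))
    lines <- c(
      "digraph dfg {",
      paste0("  ", q(dfg$nodes$activity),
             " [label=", q(paste0(dfg$nodes$activity, "\\n",
                                  dfg$nodes$frequency)), "];"),
      paste0("  ", q(dfg$edges$from), " -> ", q(dfg$edges$to),
             " [label=", q(as.character(lab)), "];"),
      "}")
    writeLines(lines, path)
  } else {
    jsonlite::write_json(
      list(nodes = dfg$nodes, edges = dfg$edges,
           starts = dfg$starts, ends = dfg$ends),
      path, dataframe = "rows", auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Keep mainstream activities and major paths
#'
#' Activities are ranked by event count and kept until their cumulative count
#' reaches `activity_fraction` of all events (activities tied with the last
#' kept count are kept together); traces are rebuilt on the surviving events.
#' The directly-follows graph of the filtered log is then pruned of edges
#' whose frequency falls below the `1 - path_fraction` quantile; nodes are
#' never removed by path pruning. Fractions of 1 leave the log and graph
#' unchanged.
#'
#' @param log An [event_log()].
#' @param activity_fraction,path_fraction Fractions in `(0, 1]`.
#' @return List with the filtered `log` and the pruned `dfg`.
#' @export
filter_mainstream <- function(log, activity_fraction = 1, path_fraction = 1) {
  stopifnot(inherits(log, "event_log"),
            activity_fraction > 0, activity_fraction <= 1,
            path_fraction > 0, path_fraction <= 1)
  events <- tidy(log)
  counts <- events |>
    count(.data$activity, sort = TRUE, name = "frequency")
  cum <- cumsum(counts$frequency)
  k <- which(cum >= activity_fraction * sum(counts$frequency))[1]
  thresh <- counts$frequency[k]
  keep <- counts$activity[counts$frequency >= thresh]
  filtered <- events |> filter(.data$activity %in% keep)
  if (nrow(filtered) == 0 || length(unique(filtered$case_id)) == 0) {
    abort("filtering removed every event; use larger fractions")
  }
  flog <- event_log(filtered,
                    cases = log_cases(log) |>
                      filter(.data$case_id %in% filtered$case_id),
                    process_type = log_process_type(log))
  dfg <- discover_dfg(flog)
  if (nrow(dfg$edges) > 0) {
    cut <- quantile(dfg$edges$frequency, 1 - path_fraction, type = 1)
    dfg$edges <- dfg$edges |> filter(.data$frequency >= cut)
  }
  list(log = flog, dfg = dfg)
}

#' Trace variants of an event log
#'
#' Cases sharing the exact activity sequence form a variant; variants are
#' ranked by case count, with supports over the number of cases.
#'
#' @param log An [event_log()].
#' @return A tibble `variant`, `n_cases`, `support`, `rank` (class
#'   `variant_table`).
#' @export
compute_variants <- function(log) {
  stopifnot(inherits(log, "event_log"))
  events <- tidy(log)
  if (nrow(events) == 0) abort("cannot compute variants of an empty log")
  out <- events |>
    group_by(.data$case_id) |>
    summarise(variant = paste(.data$activity, collapse = " > "),
              .groups = "drop") |>
    count(.data$variant, name = "n_cases", sort = TRUE) |>
    mutate(support = .data$n_cases / sum(.data$n_cases),
           rank = row_number())
  class(out) <- c("variant_table", class(out))
  out
}

#' Dotted-chart coordinates
#'
#' One point per event: the case index (cases ordered by ascending start time
#' or by descending duration), a time coordinate (absolute, or offset in
#' seconds from the case start) and the activity class.
#'
#' @param log An [event_log()].
#' @param sort `"start_time"` (ascending) or `"duration"` (descending).
#' @param time_axis `"absolute"` timestamps or `"relative"` offsets.
#' @return A tibble `case_index` (0-based, contiguous), `case_id`, `time`,
#'   `activity` (class `dotted_chart`).
#' @export
dotted_chart <- function(log, sort = c("start_time", "duration"),
                         time_axis = c("absolute", "relative")) {
  sort <- match.arg(sort)
  time_axis <- match.arg(time_axis)
  events <- tidy(log)
  if (nrow(events) == 0) abort("cannot chart an empty log")
  spans <- events |>
    group_by(.data$case_id) |>
    summarise(start = min(.data$timestamp),
              duration = as.double(max(.data$timestamp) - min(.data$timestamp),
                                   units = "secs"), .groups = "drop")
  spans <- if (sort == "start_time") arrange(spans, .data$start, .data$case_id)
           else arrange(spans, desc(.data$duration), .data$case_id)
  spans$case_index <- seq_len(nrow(spans)) - 1L
  out <- events |>
    left_join(spans, by = "case_id") |>
    mutate(time = if (time_axis == "absolute") .data$timestamp
           else as.double(.data$timestamp - .data$start, units = "secs")) |>
    select("case_index", "case_id", "time", "activity") |>
    arrange(.data$case_index, .data$time)
  class(out) <- c("dotted_chart", class(tibble()))
  attr(out, "sort") <- sort
  attr(out, "time_axis") <- time_axis
  out
}

#' @rdname dotted_chart
#' @param object A `dotted_chart`.
#' @param ... Unused.
#' @export
autoplot.dotted_chart <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$time, y = .data$case_index,
                               colour = .data$activity)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.7) +
    ggplot2::labs(x = paste0("time (", attr(object, "time_axis"), ")"),
                  y = paste0("case (sorted by ", attr(object, "sort"), ")"),
                  title = "dotted chart") +
    ggplot2::theme_minimal()
}

#' Length-of-stay summary of a log
#'
#' Sample statistics (sd with the n-1 denominator) of the LOS case attribute
#' (days for inpatient, hours for ER logs). A single case reports sd 0 with
#' `degenerate = TRUE`.
#'
#' @param log An [event_log()] whose cases carry `los_days` or `los_hours`.
#' @param attribute Case attribute to summarise; auto-detected by default.
#' @return One-row tibble `n_cases`, `mean`, `sd`, `median`, `unit`,
#'   `degenerate`.
#' @export
los_summary <- function(log, attribute = NULL) {
  cases <- log_cases(log)
  if (is.null(attribute)) {
    attribute <- intersect(c("los_days", "los_hours"), names(cases))[1]
    if (is.na(attribute)) abort("no LOS case attribute (los_days / los_hours) found")
  }
  if (!attribute %in% names(cases)) {
    abort(paste0("case attribute not found: ", attribute))
  }
  los <- cases[[attribute]]
  if (anyNA(los)) {
    abort(paste0("LOS missing for case(s): ",
                 paste(cases$case_id[is.na(los)], collapse = ", ")))
  }
  degenerate <- length(los) < 2L
  tibble(n_cases = length(los), mean = mean(los),
         sd = if (degenerate) 0 else sd(los), median = median(los),
         unit = sub("^los_", "", attribute), degenerate = degenerate)
}
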