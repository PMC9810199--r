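#' Build operation-anchored case profiles
#'
#' A case profile is the set of distinct (relative day, concept, source table)
#' order entries of one case, with calendar days counted from the anchor
#' (operation) event: the earliest event carrying `anchor_concept_id` in the
#' case. The anchor event itself is excluded; entries outside `day_window` are
#' dropped. Cases without an anchor are dropped with a warning and counted in
#' the `"dropped_cases"` attribute.
#'
#' @param log An [event_log()] whose events carry `concept_id` and
#'   `source_table`.
#' @param anchor_concept_id Concept id(s) identifying the operation event.
#' @param day_window Integer `[d_min, d_max]` of relative days to keep.
#' @return A `case_profiles` tibble with columns `case_id`, `relative_day`,
#'   `concept_id`, `source_table`, `n` (occurrence count; profile membership
#'   is presence, not multiplicity).
#' @export
build_case_profiles <- function(log, anchor_concept_id, day_window = c(-1L, 2L)) {
  stopifnot(inherits(log, "event_log"), length(day_window) == 2L,
            day_window[1] <= day_window[2])
  events <- tidy(log)
  anchors <- events |>
    filter(.data$concept_id %in% anchor_concept_id) |>
    group_by(.data$case_id) |>
    slice(1L) |>
    ungroup() |>
    select("case_id", anchor_event_id = "event_id",
           anchor_date = "timestamp") |>
    mutate(anchor_date = as.Date(.data$anchor_date, tz = "UTC"))
  all_cases <- unique(events$case_id)
  dropped <- setdiff(all_cases, anchors$case_id)
  if (length(dropped) > 0) {
    warn(paste0(length(dropped), " case(s) lack an anchor event and were dropped"))
  }
  entries <- events |>
    semi_join(anchors, by = "case_id") |>
    left_join(anchors, by = "case_id") |>
    filter(.data$event_id != .data$anchor_event_id) |>
    mutate(relative_day = as.integer(as.Date(.data$timestamp, tz = "UTC") -
                                       .data$anchor_date)) |>
    filter(.data$relative_day >= day_window[1],
           .data$relative_day <= day_window[2]) |>
    count(.data$case_id, .data$relative_day, .data$concept_id,
          .data$source_table)
  case_profiles(entries, case_ids = anchors$case_id,
                anchors = anchors, day_window = day_window,
                dropped_cases = dropped)
}

#' Construct a case-profile set from an entry table
#'
#' @param entries Tibble with columns `case_id`, `relative_day`, `concept_id`,
#'   `source_table` (and optionally `n`).
#' @param case_ids All case ids in the set (cases may have empty profiles);
#'   defaults to the ids appearing in `entries`.
#' @param anchors,day_window,dropped_cases Optional provenance attributes.
#' @return A `case_profiles` tibble.
#' @export
case_profiles <- function(entries, case_ids = NULL, anchors = NULL,
                          day_window = NULL, dropped_cases = character(0)) {
  entries <- as_tibble(entries)
  req <- c("case_id", "relative_day", "concept_id", "source_table")
  missing <- setdiff(req, names(entries))
  if (length(missing) > 0) {
    abort(paste0("profile entries lack column(s): ", paste(missing, collapse = ", ")))
  }
  entries$case_id <- as.character(entries$case_id)
  if (!"n" %in% names(entries)) entries$n <- 1L
  entries <- distinct(entries, .data$case_id, .data$relative_day,
                      .data$concept_id, .data$source_table, .keep_all = TRUE)
  case_ids <- as.character(case_ids %||% unique(entries$case_id))
  structure(entries, case_ids = case_ids, anchors = anchors,
            day_window = day_window, dropped_cases = dropped_cases,
            class = c("case_profiles", class(tibble())))
}

as_case_profiles <- function(x) {
  if (inherits(x, "case_profiles")) x else case_profiles(x)
}

profile_case_ids <- function(profiles) {
  attr(profiles, "case_ids") %||% unique(profiles$case_id)
}

entry_key <- function(relative_day, concept_id, source_table, day_aware = TRUE) {
  if (day_aware) paste(relative_day, concept_id, source_table, sep = "|")
  else paste(concept_id, source_table, sep = "|")
}

# Case x entry logical incidence structure shared by the metrics.
profile_matrix <- function(profiles, day_aware = TRUE) {
  profiles <- as_case_profiles(profiles)
  cases <- profile_case_ids(profiles)
  keys <- entry_key(profiles$relative_day, profiles$concept_id,
                    profiles$source_table, day_aware)
  entries <- profiles |>
    mutate(.key = keys) |>
    distinct(.data$.key, .keep_all = TRUE) |>
    select(".key", "relative_day", "concept_id", "source_table") |>
    arrange(.data$concept_id, .data$relative_day, .data$source_table)
  M <- matrix(FALSE, nrow = length(cases), ncol = nrow(entries),
              dimnames = list(cases, entries$.key))
  if (nrow(profiles) > 0) {
    M[cbind(match(profiles$case_id, cases), match(keys, entries$.key))] <- TRUE
  }
  list(M = M, entries = entries, cases = cases)
}

cp_keys <- function(cp, day_aware = TRUE) {
  cp <- as_tibble(cp)
  unique(entry_key(cp$relative_day, cp$concept_id, cp$source_table, day_aware))
}

#' Application rate of single pathway entries
#'
#' Fraction of cases whose profile contains the entry (on its relative day,
#' unless `day_aware = FALSE`).
#'
#' @param entry Tibble of entries (`relative_day`, `concept_id`,
#'   `source_table`), one rate per row.
#' @param profiles A [case_profiles()] set.
#' @param day_aware Match entries on their relative day (the default) or on
#'   concept and table only.
#' @return Numeric vector in `[0, 1]`.
#' @export
entry_application_rate <- function(entry, profiles, day_aware = TRUE) {
  profiles <- as_case_profiles(profiles)
  cases <- profile_case_ids(profiles)
  if (length(cases) == 0) abort("profile set is empty")
  pm <- profile_matrix(profiles, day_aware)
  keys <- entry_key(entry$relative_day, entry$concept_id, entry$source_table,
                    day_aware)
  rates <- colMeans(pm$M)
  out <- rates[match(keys, colnames(pm$M))]
  out[is.na(out)] <- 0
  unname(out)
}

#' Application rate of a clinical pathway
#'
#' Mean, over pathway entries, of the per-entry case coverage; zero for an
#' empty pathway.
#'
#' @param cp Tibble of pathway entries.
#' @inheritParams entry_application_rate
#' @return Scalar in `[0, 1]`.
#' @export
cp_application_rate <- function(cp, profiles, day_aware = TRUE) {
  if (is.null(cp) || nrow(as_tibble(cp)) == 0) return(0)
  mean(entry_application_rate(distinct(as_tibble(cp)), profiles, day_aware))
}

#' Matched ratio of a clinical pathway
#'
#' Mean, over cases, of the fraction of the case's distinct order entries that
#' the pathway covers. Cases with empty profiles are excluded from the mean
#' with a warning; an empty pathway scores zero.
#'
#' @inheritParams cp_application_rate
#' @return Scalar in `[0, 1]`.
#' @export
cp_matched_ratio <- function(cp, profiles, day_aware = TRUE) {
  profiles <- as_case_profiles(profiles)
  pm <- profile_matrix(profiles, day_aware)
  denom <- rowSums(pm$M)
  nonempty <- denom > 0
  if (any(!nonempty)) {
    warn(paste0(sum(!nonempty), " case(s) have empty profiles and are excluded ",
                "from the matched ratio"))
  }
  if (!any(nonempty)) return(0)
  if (is.null(cp) || nrow(as_tibble(cp)) == 0) return(0)
  keys <- intersect(cp_keys(cp, day_aware), colnames(pm$M))
  if (length(keys) == 0) return(0)
  matched <- rowSums(pm$M[, keys, drop = FALSE])
  mean(matched[nonempty] / denom[nonempty])
}

#' Matching rate of a clinical pathway
#'
#' The pathway-mining objective: the sum of [cp_application_rate()] and
#' [cp_matched_ratio()], in `[0, 2]`.
#'
#' @inheritParams cp_application_rate
#' @return Scalar in `[0, 2]`.
#' @export
#' @examples
#' profiles <- case_profiles(tibble::tibble(
#'   case_id = c("c1", "c1", "c2"), relative_day = 0L,
#'   concept_id = c(1L, 2L, 1L), source_table = "drug_exposure"))
#' cp <- tibble::tibble(relative_day = 0L, concept_id = 1L,
#'                      source_table = "drug_exposure")
#' cp_matching_rate(cp, profiles)  # 1.0 + mean(1/2, 1/1) = 1.75
cp_matching_rate <- function(cp, profiles, day_aware = TRUE) {
  cp_application_rate(cp, profiles, day_aware) +
    cp_matched_ratio(cp, profiles, day_aware)
}

#' Greedy matching-rate clinical-pathway mining
#'
#' Iteratively appends the candidate entry maximizing the selection criterion
#' (default: highest application rate; ties broken by smaller concept id then
#' smaller relative day), recording the application rate, matched ratio and
#' matching rate after each append. The optimal pathway size is the smallest
#' prefix length attaining the maximal matching rate over the curve.
#'
#' @param profiles A [case_profiles()] set.
#' @param k_max Longest prefix considered; defaults to all candidates, capped
#'   at 500.
#' @param selection `"application_rate"` (rank candidates once by coverage) or
#'   `"matching_gain"` (pick the entry with the largest matching-rate gain at
#'   each step).
#' @inheritParams entry_application_rate
#' @return A `clinical_pathway`: ordered `entries` (with per-entry rates), the
#'   metric `curve` (one row per prefix), and `optimal_k`.
#' @export
greedy_cp_mine <- function(profiles, k_max = NULL,
                           selection = c("application_rate", "matching_gain"),
                           day_aware = TRUE) {
  selection <- match.arg(selection)
  profiles <- as_case_profiles(profiles)
  pm <- profile_matrix(profiles, day_aware)
  n_cand <- ncol(pm$M)
  if (n_cand == 0) {
    return(new_clinical_pathway(
      entries = pm$entries, curve = tibble(k = integer(0),
                                           application_rate = numeric(0),
                                           matched_ratio = numeric(0),
                                           matching_rate = numeric(0)),
      optimal_k = 0L, day_aware = day_aware, n_cases = length(pm$cases),
      selection = selection))
  }
  k_max <- min(k_max %||% 500L, n_cand)
  rates <- colMeans(pm$M)
  denom <- rowSums(pm$M)
  nonempty <- denom > 0
  # matched-ratio gain of each entry is additive across distinct entries
  mr_gain <- colMeans(pm$M[nonempty, , drop = FALSE] /
                        denom[nonempty])
  tie_order <- order(-rates, pm$entries$concept_id, pm$entries$relative_day)
  if (selection == "application_rate") {
    ord <- tie_order[seq_len(k_max)]
  } else {
    ord <- integer(k_max)
    remaining <- rep(TRUE, n_cand)
    ar <- 0
    pos <- seq_len(n_cand)[tie_order]  # preserves tie-break preference
    for (k in seq_len(k_max)) {
      gain <- (rates - ar) / k + mr_gain
      gain[!remaining] <- -Inf
      # first index in tie-break order attaining the max gain
      best <- pos[which.max(gain[pos])]
      ord[k] <- best
      remaining[best] <- FALSE
      ar <- ar + (rates[best] - ar) / k
    }
  }
  curve <- tibble(
    k = seq_len(k_max),
    application_rate = unname(cumsum(rates[ord]) / seq_len(k_max)),
    matched_ratio = unname(cumsum(mr_gain[ord]))) |>
    mutate(matching_rate = .data$application_rate + .data$matched_ratio)
  optimal_k <- which.max(curve$matching_rate)  # smallest k on ties
  entries <- pm$entries[ord, c("relative_day", "concept_id", "source_table")]
  entries$application_rate <- unname(rates[ord])
  new_clinical_pathway(entries = entries, curve = curve,
                       optimal_k = optimal_k, day_aware = day_aware,
                       n_cases = length(pm$cases), selection = selection)
}

new_clinical_pathway <- function(entries, curve, optimal_k, day_aware,
                                 n_cases, selection) {
  structure(list(entries = as_tibble(entries), curve = curve,
                 optimal_k = as.integer(optimal_k), day_aware = day_aware,
                 n_cases = n_cases, selection = selection),
            class = "clinical_pathway")
}

#' @export
print.clinical_pathway <- function(x, ...) {
  cat("<clinical_pathway> mined from", x$n_cases, "cases;",
      nrow(x$entries), "candidate entries considered\n")
  if (x$optimal_k > 0) {
    at <- x$curve[x$optimal_k, ]
    cat(sprintf("  optimal k = %d: application rate %.4f, matched ratio %.4f, matching rate %.4f\n",
                x$optimal_k, at$application_rate, at$matched_ratio,
                at$matching_rate))
  }
  invisible(x)
}

#' @rdname greedy_cp_mine
#' @param x A `clinical_pathway`.
#' @param ... Unused.
#' @export
tidy.clinical_pathway <- function(x, ...) {
  head(x$entries, x$optimal_k)
}

#' @rdname greedy_cp_mine
#' @export
glance.clinical_pathway <- function(x, ...) {
  at <- if (x$optimal_k > 0) x$curve[x$optimal_k, ] else
    tibble(application_rate = 0, matched_ratio = 0, matching_rate = 0)
  tibble(optimal_k = x$optimal_k,
         application_rate = at$application_rate,
         matched_ratio = at$matched_ratio,
         matching_rate = at$matching_rate,
         n_candidates = nrow(x$entries),
         n_cases = x$n_cases)
}

#' @rdname greedy_cp_mine
#' @param object A `clinical_pathway`.
#' @export
autoplot.clinical_pathway <- function(object, ...) {
  d <- object$curve |>
    tidyr::pivot_longer(c("application_rate", "matched_ratio", "matching_rate"),
                        names_to = "metric", values_to = "value")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$k, y = .data$value,
                                  colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$optimal_k, linetype = "dashed") +
    ggplot2::labs(x = "number of clinical orders in the pathway",
                  y = "rate",
                  title = "Finding the optimal number of clinical orders") +
    ggplot2::theme_minimal()
}

#' Exhaustive matching-rate maximization
#'
#' Enumerates every size-`k` entry subset and returns the one maximizing the
#' matching rate; ties resolve to the subset encountered first when candidates
#' are sorted by (concept id, relative day, source table). Intended as a small
#' oracle for validating the greedy selection.
#'
#' @inheritParams greedy_cp_mine
#' @param k Subset size.
#' @param cap Largest number of subsets the search will enumerate.
#' @return List with `entries` (the argmax subset) and `matching_rate`.
#' @export
exhaustive_cp_search <- function(profiles, k, cap = 1e6, day_aware = TRUE) {
  profiles <- as_case_profiles(profiles)
  pm <- profile_matrix(profiles, day_aware)
  n <- ncol(pm$M)
  if (k > n) abort("k exceeds the number of candidate entries")
  if (choose(n, k) > cap) {
    abort(paste0("choose(", n, ", ", k, ") exceeds the enumeration cap; ",
                 "reduce the instance or raise cap"))
  }
  combos <- combn(n, k)
  best_rate <- -Inf
  best <- NULL
  for (j in seq_len(ncol(combos))) {
    cp <- pm$entries[combos[, j], c("relative_day", "concept_id", "source_table")]
    rate <- suppressWarnings(cp_matching_rate(cp, profiles, day_aware))
    if (rate > best_rate + 1e-12) {
      best_rate <- rate
      best <- cp
    }
  }
  list(entries = best, matching_rate = best_rate)
}

day_group_label <- function(d) {
  dplyr::case_when(
    d == 0 ~ "OP day",
    d < 0 ~ paste0(-d, ifelse(d == -1, " day before", " days before")),
    TRUE ~ paste0(d, ifelse(d == 1, " day after", " days after")))
}

#' Day-grouped clinical-pathway report
#'
#' Renders the selected pathway entries grouped by relative day ("1 day
#' before", "OP day", "2 days after", ...) and source table, each order shown
#' as `"<concept_id>(<concept name>)"`.
#'
#' @param cp A `clinical_pathway` (its optimal prefix is reported) or a tibble
#'   of entries.
#' @param dataset A [cdm_dataset()] supplying the vocabulary.
#' @return Tibble with columns `relative_day`, `day_label`, `source_table`,
#'   `concept_id`, `order` and a collapsed `orders` column per group in the
#'   `"groups"` attribute.
#' @export
cp_report <- function(cp, dataset) {
  entries <- if (inherits(cp, "clinical_pathway")) tidy(cp) else as_tibble(cp)
  if (nrow(entries) == 0) abort("cannot report an empty pathway")
  out <- entries |>
    mutate(day_label = day_group_label(.data$relative_day),
           order = paste0(.data$concept_id, "(",
                          resolve_concept(dataset, .data$concept_id), ")")) |>
    arrange(.data$relative_day, .data$source_table, .data$concept_id) |>
    select("relative_day", "day_label", "source_table", "concept_id", "order")
  groups <- out |>
    group_by(.data$relative_day, .data$day_label, .data$source_table) |>
    summarise(orders = paste(.data$order, collapse = ", "), .groups = "drop")
  attr(out, "groups") <- groups
  out
}
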