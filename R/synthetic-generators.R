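# Synthetic OMOP CDM generators with planted ground truth.
#
# Each generator draws per-patient sub-streams from config$seed, materializes
# visits and clinical events, and returns both the dataset and the ground
# truth (planted pathway, probabilities, transition matrix, true sequences)
# needed for parameter-recovery tests.

# Uniform time of day on [from_h, to_h) attached to a calendar date.
rand_time <- function(date, from_h = 8, to_h = 18, n = 1L) {
  secs <- runif(n, from_h * 3600, to_h * 3600)
  as.POSIXct(as.character(date), tz = "UTC") + floor(secs)
}

sample_named <- function(dist, n = 1L) {
  as.integer(sample(names(dist), n, replace = TRUE, prob = dist))
}

# Long event rows -> canonical per-table CDM tibbles with sequential row ids.
events_to_tables <- function(long) {
  sch <- cdm_event_schema()
  out <- list()
  for (tb in unique(long$source_table)) {
    x <- long |>
      filter(.data$source_table == tb) |>
      arrange(.data$visit_occurrence_id, .data$event_datetime, .data$concept_id)
    row <- sch[sch$table == tb, ]
    t <- tibble(
      id = seq_len(nrow(x)),
      visit_occurrence_id = x$visit_occurrence_id,
      person_id = x$person_id,
      concept = x$concept_id,
      datetime = x$event_datetime,
      date_only = x$date_only,
      provider_id = x$provider_id
    )
    names(t)[names(t) == "id"] <- row$id_col
    names(t)[names(t) == "concept"] <- row$concept_col
    names(t)[names(t) == "datetime"] <- row$datetime_col
    out[[tb]] <- t
  }
  out
}

synthetic_vocabulary <- function(cfg, extra = NULL) {
  voc <- base_concepts()
  add <- list(tibble(concept_id = cfg$surgery_concept_id,
                     concept_name = "Total laparoscopic hysterectomy (synthetic)",
                     domain_id = "Procedure"))
  if (nrow(cfg$planted_cp) > 0) {
    add <- c(add, list(tibble(
      concept_id = cfg$planted_cp$concept_id,
      concept_name = paste0("planted order ", seq_len(nrow(cfg$planted_cp))),
      domain_id = "Other")))
  }
  if (nrow(cfg$noise_orders) > 0) {
    add <- c(add, list(tibble(
      concept_id = cfg$noise_orders$concept_id,
      concept_name = paste0("noise order ", seq_len(nrow(cfg$noise_orders))),
      domain_id = "Other")))
  }
  if (!is.null(extra)) add <- c(add, list(extra))
  bind_rows(c(list(voc), add)) |> distinct(.data$concept_id, .keep_all = TRUE)
}

default_providers <- function(n = 5L) {
  tibble(provider_id = seq_len(n),
         provider_name = paste0("provider_", seq_len(n)),
         care_site_id = 1L)
}

default_care_sites <- function() {
  tibble(care_site_id = 1L, care_site_name = "synthetic tertiary hospital")
}

new_person_row <- function(person_id) {
  tibble(person_id = person_id,
         gender_concept_id = sample(c(8532L, 8507L), 1L),
         year_of_birth = sample(1940:1990, 1L))
}

#' Generate a synthetic inpatient surgery cohort
#'
#' One inpatient visit (visit concept 9201) per patient, containing exactly one
#' surgery event (`procedure_occurrence`, `config$surgery_concept_id`) on a day
#' at least one day after admission. Each planted pathway entry `(d, c)` is
#' applied independently per case with its configured probability on calendar
#' day `anchor + d`; noise orders are day-independent Bernoulli draws over the
#' whole stay. The anchor day is placed so that every planted relative day
#' falls inside the stay, keeping empirical application rates unbiased.
#'
#' @param config A [synthetic_config()].
#' @return A list with elements `dataset` (a [cdm_dataset()]) and `truth`
#'   (planted pathway, noise table, per-case anchors).
#' @export
#' @examples
#' sim <- generate_inpatient_cohort(synthetic_config(seed = 1, n_patients = 5))
#' sim$dataset$visit_occurrence
generate_inpatient_cohort <- function(config) {
  validate_synthetic_config(config)
  planted <- config$planted_cp
  noise <- config$noise_orders
  dmin <- if (nrow(planted) > 0) min(planted$relative_day) else 0L
  dmax <- if (nrow(planted) > 0) max(planted$relative_day) else 0L
  period <- config$study_period
  persons <- visits <- anchors <- vector("list", config$n_patients)
  ev <- vector("list", config$n_patients)
  for (i in seq_len(config$n_patients)) {
    res <- with_seed(patient_seed(config$seed, i), {
      L <- sample(config$los_distribution$days, 1L,
                  prob = config$los_distribution$prob)
      max_adm <- as.integer(period[2] - period[1]) - L - 1L
      adm_date <- period[1] + sample.int(max_adm + 1L, 1L) - 1L
      lo <- max(1L, -dmin); hi <- min(L - 1L, L - dmax)
      a <- if (lo == hi) lo else sample(lo:hi, 1L)
      anchor_date <- adm_date + a
      person <- new_person_row(i)
      visit <- tibble(
        visit_occurrence_id = i, person_id = i, visit_concept_id = 9201L,
        visit_start_datetime = rand_time(adm_date, 8, 12),
        visit_end_datetime = rand_time(adm_date + L, 10, 16),
        provider_id = sample(1:5, 1L), care_site_id = 1L,
        admitting_source_concept_id = 8536L, discharge_to_concept_id = 8536L)
      rows <- list(tibble(
        source_table = "procedure_occurrence", visit_occurrence_id = i,
        person_id = i, concept_id = config$surgery_concept_id,
        event_datetime = rand_time(anchor_date, 9, 12),
        date_only = FALSE, provider_id = sample(1:5, 1L)))
      if (nrow(planted) > 0) {
        hit <- runif(nrow(planted)) < planted$occurrence_probability
        if (any(hit)) {
          ph <- planted[hit, ]
          rows <- c(rows, list(tibble(
            source_table = ph$source_table, visit_occurrence_id = i,
            person_id = i, concept_id = ph$concept_id,
            event_datetime = rand_time(anchor_date + ph$relative_day, 8, 18,
                                       n = nrow(ph)),
            date_only = FALSE,
            provider_id = sample(1:5, nrow(ph), replace = TRUE))))
        }
      }
      if (nrow(noise) > 0) {
        for (day in 0:L) {
          hit <- runif(nrow(noise)) < noise$probability
          if (any(hit)) {
            nh <- noise[hit, ]
            rows <- c(rows, list(tibble(
              source_table = nh$source_table, visit_occurrence_id = i,
              person_id = i, concept_id = nh$concept_id,
              event_datetime = rand_time(adm_date + day, 8, 18, n = nrow(nh)),
              date_only = FALSE,
              provider_id = sample(1:5, nrow(nh), replace = TRUE))))
          }
        }
      }
      list(person = person, visit = visit,
           anchor = tibble(person_id = i, visit_occurrence_id = i,
                           admission_date = adm_date, anchor_date = anchor_date,
                           los_days = L),
           events = list_rbind(rows))
    })
    persons[[i]] <- res$person; visits[[i]] <- res$visit
    anchors[[i]] <- res$anchor; ev[[i]] <- res$events
  }
  long <- list_rbind(ev)
  tabs <- events_to_tables(long)
  tabs$person <- list_rbind(persons)
  tabs$visit_occurrence <- list_rbind(visits)
  tabs$provider <- default_providers()
  tabs$care_site <- default_care_sites()
  tabs$concept <- synthetic_vocabulary(config)
  dataset <- cdm_dataset(tabs)
  truth <- list(kind = "inpatient", seed = config$seed,
                planted_cp = planted, noise_orders = noise,
                anchors = list_rbind(anchors),
                surgery_concept_id = config$surgery_concept_id)
  list(dataset = dataset, truth = truth)
}

#' Generate synthetic outpatient visits
#'
#' Visits with visit concept 9202 whose events are drawn from the six
#' outpatient source tables (condition, measurement, drug, procedure, cost,
#' observation) with per-table Poisson counts. A per-table fraction of
#' condition/drug/cost rows is degraded to date-only timestamps, exercising
#' [repair_dateonly_timestamps()].
#'
#' @inheritParams generate_inpatient_cohort
#' @return A list `dataset` / `truth` (per-table means, date-only fractions,
#'   per-visit counts).
#' @export
generate_outpatient_visits <- function(config) {
  validate_synthetic_config(config)
  op <- config$outpatient
  period <- config$study_period
  persons <- vector("list", config$n_patients)
  visits <- ev <- list()
  vid <- 0L
  for (i in seq_len(config$n_patients)) {
    res <- with_seed(patient_seed(config$seed, i), {
      n_vis <- 1L + rpois(1L, op$visits_lambda)
      dates <- sort(period[1] +
                      sample.int(as.integer(period[2] - period[1]) - 1L, n_vis))
      vrows <- erows <- vector("list", n_vis)
      for (k in seq_len(n_vis)) {
        vstart <- rand_time(dates[k], 8, 16)
        vend <- vstart + floor(runif(1, 1, 4) * 3600)
        vrows[[k]] <- tibble(
          visit_occurrence_id = NA_integer_, person_id = i,
          visit_concept_id = 9202L, visit_start_datetime = vstart,
          visit_end_datetime = vend, provider_id = sample(1:5, 1L),
          care_site_id = 1L, admitting_source_concept_id = NA_integer_,
          discharge_to_concept_id = NA_integer_)
        per_tab <- list()
        for (tb in names(op$event_means)) {
          n_ev <- rpois(1L, op$event_means[[tb]])
          if (n_ev == 0) next
          ts <- vstart + floor(sort(runif(n_ev, 60, as.double(vend - vstart,
                                                              units = "secs") - 60)))
          d_only <- runif(n_ev) < (op$date_only_fraction[tb] %||% 0)
          d_only[is.na(d_only)] <- FALSE
          ts[d_only] <- as.POSIXct(as.character(dates[k]), tz = "UTC")
          per_tab[[tb]] <- tibble(
            source_table = tb, visit_occurrence_id = NA_integer_,
            person_id = i, concept_id = 7000000L + sample.int(50L, n_ev,
                                                              replace = TRUE),
            event_datetime = ts, date_only = d_only,
            provider_id = sample(1:5, n_ev, replace = TRUE))
        }
        erows[[k]] <- list_rbind(per_tab)
      }
      list(person = new_person_row(i), visits = vrows, events = erows)
    })
    persons[[i]] <- res$person
    for (k in seq_along(res$visits)) {
      vid <- vid + 1L
      res$visits[[k]]$visit_occurrence_id <- vid
      visits[[vid]] <- res$visits[[k]]
      if (!is.null(res$events[[k]]) && nrow(res$events[[k]]) > 0) {
        res$events[[k]]$visit_occurrence_id <- vid
        ev[[length(ev) + 1L]] <- res$events[[k]]
      }
    }
  }
  long <- list_rbind(ev)
  tabs <- events_to_tables(long)
  tabs$person <- list_rbind(persons)
  tabs$visit_occurrence <- list_rbind(visits)
  tabs$provider <- default_providers()
  tabs$care_site <- default_care_sites()
  op_concepts <- tibble(concept_id = 7000000L + 1:50,
                        concept_name = paste0("outpatient order ", 1:50),
                        domain_id = "Other")
  tabs$concept <- synthetic_vocabulary(config, extra = op_concepts)
  dataset <- cdm_dataset(tabs)
  counts <- long |> count(.data$visit_occurrence_id, .data$source_table)
  truth <- list(kind = "outpatient", seed = config$seed,
                event_means = op$event_means,
                date_only_fraction = op$date_only_fraction,
                n_visits = vid, per_visit_counts = counts)
  list(dataset = dataset, truth = truth)
}

#' Generate synthetic emergency-room visits
#'
#' One ER visit (visit concept 9203) per patient. Admission sources and
#' discharge destinations are drawn from configured distributions over the
#' standard concept ids (8536, 44790567, 8716, 8717, 8756); stay duration in
#' hours follows a gamma law matched to the configured mean and standard
#' deviation; in-visit events come from measurement, drug_exposure,
#' observation and note.
#'
#' @inheritParams generate_inpatient_cohort
#' @return A list `dataset` / `truth` (the configured distributions and LOS
#'   moments).
#' @export
generate_er_visits <- function(config) {
  validate_synthetic_config(config)
  er <- config$er
  period <- config$study_period
  m <- er$mean_los_hours; s <- er$sd_los_hours
  shape <- (m / s)^2; rate <- m / s^2
  persons <- visits <- vector("list", config$n_patients)
  ev <- list()
  for (i in seq_len(config$n_patients)) {
    res <- with_seed(patient_seed(config$seed, i), {
      date <- period[1] + sample.int(as.integer(period[2] - period[1]) - 1L, 1L) - 1L
      vstart <- rand_time(date, 0, 20)
      los_h <- max(stats::rgamma(1L, shape = shape, rate = rate), 0.2)
      vend <- vstart + floor(los_h * 3600)
      visit <- tibble(
        visit_occurrence_id = i, person_id = i, visit_concept_id = 9203L,
        visit_start_datetime = vstart, visit_end_datetime = vend,
        provider_id = sample(1:5, 1L), care_site_id = 1L,
        admitting_source_concept_id = sample_named(er$source_distribution),
        discharge_to_concept_id = sample_named(er$discharge_distribution))
      per_tab <- list()
      for (tb in names(er$event_means)) {
        n_ev <- rpois(1L, er$event_means[[tb]])
        if (n_ev == 0) next
        span <- as.double(vend - vstart, units = "secs")
        ts <- vstart + floor(sort(runif(n_ev, 1, max(span - 1, 2))))
        per_tab[[tb]] <- tibble(
          source_table = tb, visit_occurrence_id = i, person_id = i,
          concept_id = 7100000L + sample.int(20L, n_ev, replace = TRUE),
          event_datetime = ts, date_only = FALSE,
          provider_id = sample(1:5, n_ev, replace = TRUE))
      }
      list(person = new_person_row(i), visit = visit,
           events = list_rbind(per_tab))
    })
    persons[[i]] <- res$person; visits[[i]] <- res$visit
    if (!is.null(res$events) && nrow(res$events) > 0) {
      ev[[length(ev) + 1L]] <- res$events
    }
  }
  long <- list_rbind(ev)
  tabs <- events_to_tables(long)
  tabs$person <- list_rbind(persons)
  tabs$visit_occurrence <- list_rbind(visits)
  tabs$provider <- default_providers()
  tabs$care_site <- default_care_sites()
  er_concepts <- tibble(concept_id = 7100000L + 1:20,
                        concept_name = paste0("er order ", 1:20),
                        domain_id = "Other")
  tabs$concept <- synthetic_vocabulary(config, extra = er_concepts)
  dataset <- cdm_dataset(tabs)
  truth <- list(kind = "er", seed = config$seed,
                source_distribution = er$source_distribution,
                discharge_distribution = er$discharge_distribution,
                mean_los_hours = m, sd_los_hours = s)
  list(dataset = dataset, truth = truth)
}

journey_visit_concepts <- function() {
  c(Outpatient = 9202L, Inpatient = 9201L, ER = 9203L, Checkup = 9205L)
}

#' Generate synthetic multi-year patient journeys
#'
#' Each patient's visit sequence is a realization of a visit-type Markov chain
#' over Outpatient / Inpatient / ER / Checkup until the End state or the
#' per-patient cap. Visits are materialized with strictly increasing,
#' non-overlapping windows and a small per-type event mix (inpatient visits
#' contain one surgery event). The realized sequences and the transition
#' matrix are returned as ground truth for chain-recovery tests.
#'
#' @inheritParams generate_inpatient_cohort
#' @return A list `dataset` / `truth` (`sequences` tibble, transition matrix,
#'   initial distribution).
#' @export
generate_patient_journeys <- function(config) {
  validate_synthetic_config(config)
  jn <- config$journey
  states <- rownames(jn$transition)
  period <- config$study_period
  vcid <- journey_visit_concepts()
  persons <- vector("list", config$n_patients)
  visits <- ev <- seqs <- list()
  vid <- 0L
  for (i in seq_len(config$n_patients)) {
    res <- with_seed(patient_seed(config$seed, i), {
      s <- sample(names(jn$initial), 1L, prob = jn$initial)
      types <- character(0)
      while (s != "End" && length(types) < jn$cap) {
        types <- c(types, s)
        s <- sample(states, 1L, prob = jn$transition[s, ])
      }
      cur <- period[1] + sample.int(180L, 1L) - 1L
      vrows <- erows <- vector("list", length(types))
      for (k in seq_along(types)) {
        ty <- types[k]
        L <- if (ty == "Inpatient") sample(3:7, 1L) else 0L
        vstart <- rand_time(cur, 8, 12)
        vend <- if (L > 0) rand_time(cur + L, 10, 16) else vstart + floor(runif(1, 1, 6) * 3600)
        vrows[[k]] <- tibble(
          visit_occurrence_id = NA_integer_, person_id = i,
          visit_concept_id = vcid[[ty]], visit_start_datetime = vstart,
          visit_end_datetime = vend, provider_id = sample(1:5, 1L),
          care_site_id = 1L,
          admitting_source_concept_id =
            if (ty == "ER") sample_named(config$er$source_distribution) else NA_integer_,
          discharge_to_concept_id =
            if (ty == "ER") sample_named(config$er$discharge_distribution) else NA_integer_)
        mk <- function(tb, cid, dt) tibble(
          source_table = tb, visit_occurrence_id = NA_integer_, person_id = i,
          concept_id = cid, event_datetime = dt, date_only = FALSE,
          provider_id = sample(1:5, 1L))
        erows[[k]] <- switch(ty,
          Outpatient = bind_rows(
            mk("condition_occurrence", 7200001L, vstart + 600),
            mk("drug_exposure", 7200002L, vstart + 1800),
            mk("cost", 7200003L, vstart + 3000)),
          Inpatient = bind_rows(
            mk("procedure_occurrence", config$surgery_concept_id,
               rand_time(cur + 1L, 9, 12)),
            mk("drug_exposure", 7200002L, rand_time(cur + 1L, 13, 18)),
            mk("drug_exposure", 7200004L, rand_time(cur + 2L, 8, 18))),
          ER = bind_rows(
            mk("measurement", 7200005L, vstart + 900),
            mk("observation", 7200006L, vstart + 1800)),
          Checkup = bind_rows(
            mk("measurement", 7200005L, vstart + 600),
            mk("measurement", 7200007L, vstart + 1500)))
        cur <- as.Date(vend, tz = "UTC") + 3L + rpois(1L, 25L)
      }
      list(person = new_person_row(i), types = types,
           visits = vrows, events = erows)
    })
    persons[[i]] <- res$person
    if (length(res$types) > 0) {
      ids <- integer(length(res$types))
      for (k in seq_along(res$types)) {
        vid <- vid + 1L
        ids[k] <- vid
        res$visits[[k]]$visit_occurrence_id <- vid
        res$events[[k]]$visit_occurrence_id <- vid
        visits[[vid]] <- res$visits[[k]]
        ev[[length(ev) + 1L]] <- res$events[[k]]
      }
      seqs[[length(seqs) + 1L]] <- tibble(
        person_id = i, step = seq_along(res$types), visit_type = res$types,
        visit_occurrence_id = ids)
    }
  }
  long <- list_rbind(ev)
  tabs <- if (nrow(long) > 0) events_to_tables(long) else list()
  tabs$person <- list_rbind(persons)
  tabs$visit_occurrence <- list_rbind(visits)
  tabs$provider <- default_providers()
  tabs$care_site <- default_care_sites()
  jn_concepts <- tibble(concept_id = 7200000L + 1:7,
                        concept_name = paste0("journey order ", 1:7),
                        domain_id = "Other")
  tabs$concept <- synthetic_vocabulary(config, extra = jn_concepts)
  dataset <- cdm_dataset(tabs)
  truth <- list(kind = "journey", seed = config$seed,
                sequences = list_rbind(seqs),
                transition = jn$transition, initial = jn$initial)
  list(dataset = dataset, truth = truth)
}

#' Run one of the synthetic generators by process type
#'
#' @param config A [synthetic_config()].
#' @param type One of `"inpatient"`, `"outpatient"`, `"er"`,
#'   `"patient_journey"`.
#' @return A list `dataset` / `truth` as documented on the per-type generator.
#' @export
simulate_cdm <- function(config, type = c("inpatient", "outpatient", "er",
                                          "patient_journey")) {
  type <- match.arg(type)
  switch(type,
    inpatient = generate_inpatient_cohort(config),
    outpatient = generate_outpatient_visits(config),
    er = generate_er_visits(config),
    patient_journey = generate_patient_journeys(config))
}
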