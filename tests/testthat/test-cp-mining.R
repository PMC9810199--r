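two_case_profiles <- function() {
  # case1 has entries {A, B}, case2 has {A}
  case_profiles(tibble::tibble(
    case_id = c("c1", "c1", "c2"),
    relative_day = 0L,
    concept_id = c(1L, 2L, 1L),
    source_table = "drug_exposure"))
}

entry <- function(concept_id, day = 0L, table = "drug_exposure") {
  tibble::tibble(relative_day = day, concept_id = concept_id,
                 source_table = table)
}

test_that("case profiles anchor relative days on the operation date", {
  events <- tibble::tibble(
    case_id = "c1",
    event_id = paste0("e", 1:4),
    activity = "x",
    timestamp = ts(c("2021-08-02 09:30:00",  # anchor (surgery)
                     "2021-08-02 11:00:00",  # OP day
                     "2021-08-01 10:00:00",  # 1 day before
                     "2021-08-07 10:00:00")),# +5, outside window
    source_table = c("procedure_occurrence", "drug_exposure",
                     "drug_exposure", "drug_exposure"),
    event_row_id = 1:4,
    concept_id = c(4300001L, 11L, 12L, 13L))
  prof <- build_case_profiles(event_log(events), 4300001L, day_window = c(-1L, 2L))
  expect_setequal(prof$relative_day, c(0L, -1L))
  expect_setequal(prof$concept_id, c(11L, 12L))
  # the anchor event itself and the +5 event are excluded
  expect_false(any(prof$concept_id %in% c(4300001L, 13L)))
})

test_that("cases without an anchor are dropped with a warning", {
  events <- tibble::tibble(
    case_id = c("c1", "c2"), event_id = c("e1", "e2"), activity = "x",
    timestamp = ts("2021-08-02 09:00:00"),
    source_table = "drug_exposure", event_row_id = 1:2,
    concept_id = c(4300001L, 99L))
  expect_warning(prof <- build_case_profiles(event_log(events), 4300001L),
                 "lack an anchor")
  expect_equal(attr(prof, "dropped_cases"), "c2")
})

test_that("entry application rate is the case coverage fraction", {
  prof <- two_case_profiles()
  expect_equal(entry_application_rate(entry(1L), prof), 1.0)
  expect_equal(entry_application_rate(entry(2L), prof), 0.5)
  expect_equal(entry_application_rate(entry(99L), prof), 0.0)
  # 3 of 8 cases
  prof8 <- case_profiles(tibble::tibble(
    case_id = paste0("c", 1:8), relative_day = 0L,
    concept_id = c(1L, 1L, 1L, 2L, 2L, 2L, 2L, 2L),
    source_table = "drug_exposure"))
  expect_equal(entry_application_rate(entry(1L), prof8), 0.375)
  expect_error(entry_application_rate(entry(1L), case_profiles(
    tibble::tibble(case_id = character(0), relative_day = integer(0),
                   concept_id = integer(0), source_table = character(0)))),
    "empty")
})

test_that("pathway application rate averages entry rates; empty pathway is 0", {
  prof <- two_case_profiles()
  cp <- dplyr::bind_rows(entry(1L), entry(2L))  # rates 1.0 and 0.5
  expect_equal(cp_application_rate(cp, prof), 0.75)
  expect_equal(cp_application_rate(entry(1L), prof),
               entry_application_rate(entry(1L), prof))
  expect_equal(cp_application_rate(cp[0, ], prof), 0)
})

test_that("matched ratio averages per-case coverage of distinct entries", {
  prof <- two_case_profiles()
  # cp = {A}: case1 covers 1/2, case2 covers 1/1
  expect_equal(cp_matched_ratio(entry(1L), prof), 0.75)
  # cp covering everything scores 1
  expect_equal(cp_matched_ratio(dplyr::bind_rows(entry(1L), entry(2L)), prof), 1.0)
  expect_equal(cp_matched_ratio(entry(1L)[0, ], prof), 0)
})

test_that("matching rate is the sum of its components", {
  prof <- two_case_profiles()
  expect_equal(cp_matching_rate(entry(1L), prof), 1.0 + 0.75)
  expect_equal(cp_matching_rate(entry(1L)[0, ], prof), 0)
})

test_that("the additive identity holds on random instances", {
  set.seed(101)
  for (i in 1:100) {
    prof <- random_profiles(n_cases = sample(5:25, 1),
                            n_concepts = sample(4:12, 1))
    cp <- random_cp(prof, k = sample(1:5, 1))
    expect_equal(cp_matching_rate(cp, prof),
                 cp_application_rate(cp, prof) + cp_matched_ratio(cp, prof),
                 tolerance = 1e-12)
    expect_gte(cp_application_rate(cp, prof), 0)
    expect_lte(cp_application_rate(cp, prof), 1)
    expect_gte(cp_matched_ratio(cp, prof), 0)
    expect_lte(cp_matched_ratio(cp, prof), 1)
  }
})

test_that("greedy selection ranks by application rate with deterministic ties", {
  prof <- two_case_profiles()
  cp <- greedy_cp_mine(prof)
  # A (rate 1.0) is selected before B (0.5)
  expect_equal(cp$entries$concept_id[1], 1L)
  # equal rates break ties by ascending concept id
  prof_tie <- case_profiles(tibble::tibble(
    case_id = c("c1", "c1", "c2", "c2"), relative_day = 0L,
    concept_id = c(5L, 3L, 5L, 3L), source_table = "drug_exposure"))
  cp_tie <- greedy_cp_mine(prof_tie)
  expect_equal(cp_tie$entries$concept_id, c(3L, 5L))
})

test_that("the greedy curve matches direct metric evaluation at every prefix", {
  set.seed(202)
  prof <- random_profiles(n_cases = 15, n_concepts = 8)
  cp <- greedy_cp_mine(prof)
  for (k in seq_len(nrow(cp$curve))) {
    prefix <- head(cp$entries, k)[, c("relative_day", "concept_id", "source_table")]
    expect_equal(cp$curve$application_rate[k], cp_application_rate(prefix, prof),
                 tolerance = 1e-12)
    expect_equal(cp$curve$matched_ratio[k], cp_matched_ratio(prefix, prof),
                 tolerance = 1e-12)
  }
})

test_that("greedy curves are monotone: matched ratio up, application rate down", {
  set.seed(303)
  for (i in 1:20) {
    prof <- random_profiles(n_cases = sample(5:30, 1))
    cp <- greedy_cp_mine(prof)
    expect_true(all(diff(cp$curve$matched_ratio) >= -1e-12))
    expect_true(all(diff(cp$curve$application_rate) <= 1e-12))
    expect_true(all(cp$curve$matching_rate >= 0 & cp$curve$matching_rate <= 2))
  }
})

test_that("optimal k is the smallest argmax of the matching-rate curve", {
  set.seed(404)
  prof <- random_profiles(n_cases = 20, n_concepts = 6)
  cp <- greedy_cp_mine(prof)
  mx <- max(cp$curve$matching_rate)
  expect_equal(cp$optimal_k, min(which(cp$curve$matching_rate == mx)))
})

test_that("exhaustive search agrees with direct enumeration and bounds greedy", {
  # 2 candidates, k = 1: picks the rate-1.0 entry
  prof <- two_case_profiles()
  ex <- exhaustive_cp_search(prof, k = 1)
  expect_equal(ex$entries$concept_id, 1L)
  # k = all candidates equals the full-set matching rate
  ex_all <- exhaustive_cp_search(prof, k = 2)
  expect_equal(ex_all$matching_rate,
               cp_matching_rate(dplyr::bind_rows(entry(1L), entry(2L)), prof))
  # greedy prefix never beats the exhaustive optimum
  set.seed(505)
  for (i in 1:10) {
    prof_i <- random_profiles(n_cases = sample(5:30, 1), n_concepts = 6,
                              n_days = 2)
    k <- sample(1:3, 1)
    greedy_k <- greedy_cp_mine(prof_i, k_max = k)
    ex_k <- exhaustive_cp_search(prof_i, k = k)
    expect_lte(greedy_k$curve$matching_rate[k], ex_k$matching_rate + 1e-12)
  }
})

test_that("greedy equals exhaustive on well-separated instances", {
  set.seed(606)
  for (i in 1:5) {
    prof <- separated_profiles(n_cases = 25, k_true = 3, n_noise = 6)
    g <- greedy_cp_mine(prof, k_max = 3)
    ex <- exhaustive_cp_search(prof, k = 3)
    expect_equal(g$curve$matching_rate[3], ex$matching_rate, tolerance = 1e-12)
    expect_setequal(g$entries$concept_id[1:3], ex$entries$concept_id)
  }
})

test_that("the enumeration cap guards exhaustive search", {
  set.seed(707)
  prof <- random_profiles(n_cases = 10, n_concepts = 12, n_days = 3)
  expect_error(exhaustive_cp_search(prof, k = 5, cap = 10), "cap")
})

test_that("planted pathways are recovered from a synthetic cohort", {
  cfg <- synthetic_config(seed = 51, n_patients = 60)
  sim <- generate_inpatient_cohort(cfg)
  log <- extract_inpatient_log(sim$dataset,
                               log_spec("inpatient", period = full_period()))
  prof <- build_case_profiles(log, cfg$surgery_concept_id, c(-1L, 2L))
  cp <- greedy_cp_mine(prof)
  got <- tidy(cp)
  planted_keys <- paste(cfg$planted_cp$relative_day, cfg$planted_cp$concept_id,
                        cfg$planted_cp$source_table)
  got_keys <- paste(got$relative_day, got$concept_id, got$source_table)
  expect_gte(mean(planted_keys %in% got_keys), 0.9)  # recall
  expect_gte(mean(got_keys %in% planted_keys), 0.9)  # precision
})

test_that("day-agnostic matching merges entries across days", {
  prof <- case_profiles(tibble::tibble(
    case_id = c("c1", "c2"), relative_day = c(0L, 1L),
    concept_id = 7L, source_table = "drug_exposure"))
  expect_equal(entry_application_rate(entry(7L), prof), 0.5)
  expect_equal(entry_application_rate(entry(7L), prof, day_aware = FALSE), 1.0)
})

test_that("cp_report groups orders by day with Table-6 style labels", {
  d <- tiny_cdm()
  cp <- tibble::tibble(
    relative_day = c(-1L, 0L, 2L),
    concept_id = c(925043L, 35605373L, 19086516L),
    source_table = "drug_exposure")
  rep <- cp_report(cp, d)
  expect_equal(rep$day_label, c("1 day before", "OP day", "2 days after"))
  expect_equal(rep$order[1], "925043(bisacodyl 5 MG)")
  expect_equal(rep$order[3], "19086516(aceclofenac 100 MG)")
  groups <- attr(rep, "groups")
  expect_equal(nrow(groups), 3)
})

test_that("pathway objects expose tidy, glance and a metric curve plot", {
  set.seed(808)
  prof <- random_profiles(n_cases = 12)
  cp <- greedy_cp_mine(prof)
  expect_equal(nrow(tidy(cp)), cp$optimal_k)
  g <- glance(cp)
  expect_equal(g$matching_rate, cp$curve$matching_rate[cp$optimal_k])
  p <- autoplot(cp)
  expect_s3_class(p, "ggplot")
})
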