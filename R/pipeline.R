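#' Read and validate a pipeline run configuration
#'
#' A run configuration is a nested key/value document with a `seed`, an
#' `output_dir`, the list of enabled `stages` (any of `simulate`, `validate`,
#' `extract`, `repair`, `mine`, `discover`, `chart`) and one section per
#' stage. Validation failures name the offending field.
#'
#' @param path YAML file.
#' @return A validated `run_config` list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(paste0("config file not found: ", path))
  validate_run_config(yaml::read_yaml(path))
}

#' @rdname read_run_config
#' @param config A named list with the schema above.
#' @export
validate_run_config <- function(config) {
  problems <- character(0)
  need <- function(cond, field, msg) {
    if (!cond) problems <<- c(problems, paste0(field, ": ", msg))
  }
  need(!is.null(config$seed), "seed", "required")
  need(!is.null(config$output_dir), "output_dir", "required")
  stages <- config$stages %||% character(0)
  known <- c("simulate", "validate", "extract", "repair", "mine", "discover", "chart")
  need(all(stages %in% known), "stages",
       paste0("must be a subset of {", paste(known, collapse = ", "), "}"))
  need(length(stages) > 0, "stages", "at least one stage required")
  if ("simulate" %in% stages) {
    need(!is.null(config$synthetic$type), "synthetic.type", "required for the simulate stage")
  }
  if (any(c("validate", "extract") %in% stages) && !"simulate" %in% stages) {
    need(!is.null(config$cdm$source), "cdm.source",
         "required when extract/validate run without simulate")
  }
  if ("extract" %in% stages) {
    need(!is.null(config$extract$process_type), "extract.process_type", "required")
    need(!is.null(config$extract$period), "extract.period", "required")
  }
  if ("mine" %in% stages) {
    need(!is.null(config$mine$anchor_concept_id), "mine.anchor_concept_id", "required")
  }
  if (any(c("mine", "discover", "chart") %in% stages) && !"extract" %in% stages) {
    need(!is.null(config$log$source), "log.source",
         "required when mine/discover/chart run without extract")
  }
  if (length(problems) > 0) {
    abort(paste0("invalid run configuration:\n  ",
                 paste(problems, collapse = "\n  ")), class = "omopflow_config_error")
  }
  structure(config, class = c("run_config", "list"))
}

spec_from_config <- function(config) {
  ex <- config$extract
  cohort <- ex$cohort
  if (!is.null(cohort)) cohort$concept_ids <- as.integer(unlist(cohort$concept_ids))
  log_spec(
    process_type = ex$process_type,
    period = as.POSIXct(unlist(ex$period), tz = "UTC"),
    scope = ex$scope %||% NULL,
    cohort = cohort,
    features = ex$features %||% character(0),
    include_262 = ex$include_262 %||% TRUE,
    er_activity = ex$er_activity %||% "table",
    journey_level = ex$journey_level %||% "visit",
    journey_window = if (!is.null(ex$journey_window))
      as.POSIXct(unlist(ex$journey_window), tz = "UTC") else NULL,
    journey_activity = ex$journey_activity %||% "table",
    journey_markers = ex$journey_markers %||% FALSE)
}

#' Run the simulate/validate/extract/mine/discover workflow
#'
#' Executes the stages enabled in the configuration in order, writing every
#' artifact under `output_dir` with a provenance header (config hash, seed,
#' tool version). Given the same configuration and seed the artifact set is
#' byte-identical across runs.
#'
#' @param config A `run_config` (see [read_run_config()]) or path to one.
#' @return Invisibly, a named character vector of artifact paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  config <- validate_run_config(unclass(config))
  out_dir <- config$output_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  prov <- c(tool = paste0("omopflow ", as.character(packageVersion("omopflow"))),
            seed = as.character(config$seed),
            config_hash = rlang::hash(unclass(config)))
  stages <- config$stages
  artifacts <- character(0)
  dataset <- NULL
  truth <- NULL
  if ("simulate" %in% stages) {
    syn <- config$synthetic
    args <- syn[setdiff(names(syn), "type")]
    args$seed <- config$seed
    if (!is.null(args$study_period)) args$study_period <- as.Date(unlist(args$study_period))
    scfg <- do.call(synthetic_config, args)
    sim <- simulate_cdm(scfg, type = syn$type)
    dataset <- sim$dataset
    truth <- sim$truth
    cdm_dir <- file.path(out_dir, "cdm")
    write_cdm(dataset, cdm_dir, provenance = prov)
    truth_path <- file.path(out_dir, "ground_truth.json")
    jsonlite::write_json(c(list(provenance = as.list(prov)), truth_to_list(truth)),
                         truth_path, auto_unbox = TRUE, digits = NA,
                         dataframe = "columns")
    artifacts <- c(artifacts, cdm = cdm_dir, ground_truth = truth_path)
  } else if (!is.null(config$cdm$source)) {
    dataset <- load_cdm(config$cdm$source)
  }
  if ("validate" %in% stages) {
    report <- validate_cdm(dataset)
    vp <- file.path(out_dir, "validation_report.csv")
    writeLines(paste0("# ", names(prov), ": ", prov), vp)
    readr::write_csv(as_tibble(report), vp, append = TRUE, col_names = TRUE)
    artifacts <- c(artifacts, validation = vp)
    if (nrow(report) > 0) {
      warn(paste0("CDM validation found ", nrow(report), " violation(s)"))
    }
  }
  log <- NULL
  if ("extract" %in% stages) {
    spec <- spec_from_config(config)
    log <- extract_log(dataset, spec)
    if ("repair" %in% stages) {
      rp <- config$repair %||% list()
      log <- repair_dateonly_timestamps(
        log,
        order = rp$order %||% c("condition_occurrence", "drug_exposure", "cost"),
        gap_minutes = as.numeric(rp$gap_minutes %||% c(5, 30)))
    }
    lp <- file.path(out_dir, paste0("log.", config$log$format %||% "csv"))
    write_log(log, lp, format = config$log$format %||% "csv", provenance = prov)
    artifacts <- c(artifacts, log = lp)
  } else if (!is.null(config$log$source)) {
    log <- read_log(config$log$source, format = config$log$format %||% "csv")
  }
  if ("mine" %in% stages) {
    mn <- config$mine
    profiles <- build_case_profiles(
      log, anchor_concept_id = as.integer(mn$anchor_concept_id),
      day_window = as.integer(unlist(mn$day_window %||% c(-1L, 2L))))
    cp <- greedy_cp_mine(profiles, k_max = mn$k_max %||% NULL,
                         selection = mn$selection %||% "application_rate")
    curve_path <- file.path(out_dir, "cp_curve.csv")
    entries_path <- file.path(out_dir, "cp_entries.csv")
    report_path <- file.path(out_dir, "cp_report.csv")
    for (w in list(list(cp$curve, curve_path),
                   list(cp$entries |> mutate(selected = row_number() <= cp$optimal_k),
                        entries_path))) {
      writeLines(paste0("# ", names(prov), ": ", prov), w[[2]])
      readr::write_csv(w[[1]], w[[2]], append = TRUE, col_names = TRUE)
    }
    if (!is.null(dataset) && cp$optimal_k > 0) {
      rep <- cp_report(cp, dataset)
      writeLines(paste0("# ", names(prov), ": ", prov), report_path)
      readr::write_csv(rep, report_path, append = TRUE, col_names = TRUE)
      artifacts <- c(artifacts, cp_report = report_path)
    }
    artifacts <- c(artifacts, cp_curve = curve_path, cp_entries = entries_path)
  }
  if ("discover" %in% stages) {
    dc <- config$discover %||% list()
    res <- filter_mainstream(log,
                             activity_fraction = dc$activity_fraction %||% 1,
                             path_fraction = dc$path_fraction %||% 1)
    dot_path <- file.path(out_dir, "dfg.dot")
    json_path <- file.path(out_dir, "dfg.json")
    export_dfg(res$dfg, dot_path, format = "dot", stat = dc$stat %||% "frequency")
    export_dfg(res$dfg, json_path, format = "json")
    var_path <- file.path(out_dir, "variants.csv")
    writeLines(paste0("# ", names(prov), ": ", prov), var_path)
    readr::write_csv(compute_variants(res$log), var_path, append = TRUE,
                     col_names = TRUE)
    artifacts <- c(artifacts, dfg_dot = dot_path, dfg_json = json_path,
                   variants = var_path)
  }
  if ("chart" %in% stages) {
    ch <- config$chart %||% list()
    chart <- dotted_chart(log, sort = ch$sort %||% "start_time",
                          time_axis = ch$time_axis %||% "absolute")
    chart_path <- file.path(out_dir, "dotted_chart.csv")
    writeLines(paste0("# ", names(prov), ": ", prov), chart_path)
    out <- as_tibble(chart)
    if (inherits(out$time, "POSIXct")) out$time <- format_cdm_datetime(out$time)
    readr::write_csv(out, chart_path, append = TRUE, col_names = TRUE)
    artifacts <- c(artifacts, dotted_chart = chart_path)
  }
  invisible(artifacts)
}

truth_to_list <- function(truth) {
  out <- truth
  if (!is.null(out$transition)) {
    out$transition <- list(states = rownames(out$transition),
                           matrix = unname(apply(out$transition, 1, as.list,
                                                 simplify = FALSE)))
  }
  for (nm in names(out)) {
    if (inherits(out[[nm]], "data.frame")) {
      df <- out[[nm]]
      for (col in names(df)) if (inherits(df[[col]], "Date")) df[[col]] <- as.character(df[[col]])
      out[[nm]] <- df
    }
  }
  out
}
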