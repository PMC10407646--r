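# End-to-end orchestration: codesets -> phenotype -> cohort -> comorbidity
# -> stats, with delimited outputs and a reproducibility manifest.

#' Build a validated run configuration
#'
#' Either `input` (paths to patients/encounters/diagnoses CSVs) or
#' `generator` (arguments for [generator_config()]) must be given.
#'
#' @param input named list of file paths: `patients`, `encounters`,
#'   `diagnoses`.
#' @param generator named list of [generator_config()] arguments.
#' @param codesets path to the code-set file.
#' @param cci_map path to the Charlson mapping file.
#' @param thresholds utilization thresholds `c(p50, p75)` or `"empirical"`.
#' @param bin_width index-date matching bin width in months.
#' @param window study window (length-2 Date); defaults to the generator's
#'   window or 2008-01-01..2017-12-31.
#' @param models model set for [stratified_analysis()].
#' @param seed integer seed for index-date sampling (and the generator,
#'   unless its own seed is given).
#' @param output_dir directory for delimited outputs and the manifest;
#'   `NULL` keeps everything in memory.
#' @return a `run_config` list.
#' @export
run_config <- function(input = NULL, generator = NULL,
                       codesets = default_codesets_path(),
                       cci_map = default_cci_map_path(),
                       thresholds = c(6.6, 15.6), bin_width = 1L,
                       window = NULL,
                       models = c("bivariable", "minimal", "full"),
                       seed = 1L, output_dir = NULL) {
  if (is.null(input) && is.null(generator)) {
    stopf("run_config needs either input paths or a generator spec")
  }
  if (!is.null(input)) {
    need <- c("patients", "encounters", "diagnoses")
    if (!all(need %in% names(input))) {
      stopf("input must name files for: %s", paste(need, collapse = ", "))
    }
  }
  if (!is.null(generator)) {
    if (is.null(generator$seed)) generator$seed <- seed
    generator <- do.call(generator_config, generator)
    if (is.null(window)) window <- c(generator$window_start, generator$window_end)
  }
  window <- as.Date(window %||% c("2008-01-01", "2017-12-31"))
  structure(list(input = input, generator = generator, codesets = codesets,
                 cci_map = cci_map, thresholds = thresholds,
                 bin_width = as.integer(bin_width), window = window,
                 models = models, seed = as.integer(seed),
                 output_dir = output_dir),
            class = "run_config")
}

#' Load a run configuration from a YAML file
#'
#' @param path YAML file whose keys mirror [run_config()] arguments.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  y <- yaml::read_yaml(path)
  do.call(run_config, y)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e))
  })
}

#' Run the full analysis pipeline
#'
#' Stages, in order: load code sets and the Charlson mapping; read or
#' generate the input tables; flag self-harm encounters and take each
#' case's first event as index date; assign distribution-matched index
#' dates to non-cases; apply the two-lookback-visit eligibility rule;
#' stratify by utilization; score comorbidity; assemble the analysis table;
#' and run the stratified prevalence/OR/model analysis. Reruns with the
#' same configuration are bit-identical.
#'
#' @param config a `run_config`.
#' @return list with `cohort`, `results`, `assignments`, `exclusion_flow`,
#'   `thresholds`, `manifest` and (generated runs only) `truth`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  registry <- stage("codesets", load_codesets(config$codesets))
  cmap <- stage("cci_map", load_cci_map(config$cci_map))

  truth <- NULL
  if (!is.null(config$generator)) {
    dat <- stage("generate", generate_cohort_data(config$generator))
    patients <- dat$patients; encounters <- dat$encounters; diagnoses <- dat$diagnoses
    truth <- dat$truth
  } else {
    patients <- stage("read_input", data.table::fread(config$input$patients))
    encounters <- stage("read_input", data.table::fread(config$input$encounters))
    diagnoses <- stage("read_input", data.table::fread(config$input$diagnoses))
  }
  encounters <- data.table::as.data.table(encounters)
  encounters[, date := as.Date(date)]
  message(sprintf("input: %d patients, %d encounters, %d diagnosis rows",
                  nrow(patients), nrow(encounters), nrow(diagnoses)))

  in_window <- encounters[date >= config$window[1L] & date <= config$window[2L]]

  flagged <- stage("phenotype", {
    diag_w <- data.table::as.data.table(diagnoses)[encounter_id %in% in_window$encounter_id]
    classify_encounters(in_window, diag_w, registry)
  })
  cases <- stage("phenotype", first_self_harm(flagged))
  message(sprintf("phenotype: %d flagged encounters, %d cases", nrow(flagged), nrow(cases)))

  ctrl_candidates <- in_window[!patient_id %in% cases$patient_id, .(patient_id, date)]
  assignments <- stage("index_dates", assign_index_dates(
    cases[, .(patient_id, index_date)], ctrl_candidates,
    bin_width = config$bin_width, seed = config$seed
  ))
  n_no_candidate <- length(setdiff(unique(encounters$patient_id), assignments$patient_id))

  eligible <- stage("eligibility", apply_eligibility(encounters, assignments))
  message(sprintf("eligibility: %d of %d assigned veterans retained",
                  nrow(eligible), nrow(assignments)))

  utilization <- stage("utilization", compute_utilization(
    encounters, eligible, thresholds = config$thresholds
  ))
  thresholds_used <- attr(utilization, "thresholds")

  cohort <- stage("cohort_table", build_cohort_table(
    patients, encounters, diagnoses, eligible, utilization, registry, cmap
  ))
  results <- stage("stats", stratified_analysis(cohort, models = config$models))

  exclusion_flow <- data.table::data.table(
    step = c("all_patients", "no_in_window_encounter", "assigned_index",
             "excluded_lt2_lookback_visits", "analysis_cohort"),
    n = c(length(unique(patients$patient_id)), n_no_candidate, nrow(assignments),
          nrow(assignments) - nrow(eligible), nrow(cohort))
  )

  ref_levels <- list()
  for (s in STRATA) {
    f <- results[[s]]$fits$full %||% results[[s]]$fits$minimal
    if (!is.null(f)) ref_levels[[s]] <- f$reference_levels
  }
  manifest <- list(
    seed = config$seed,
    thresholds = as.numeric(thresholds_used),
    bin_width_months = config$bin_width,
    window = as.character(config$window),
    models = config$models,
    reference_levels = ref_levels,
    codesets_md5 = unname(tools::md5sum(config$codesets)),
    cci_map_md5 = unname(tools::md5sum(config$cci_map)),
    n_cohort = nrow(cohort),
    package_version = as.character(utils::packageVersion("ishcohort"))
  )

  out <- list(cohort = cohort, results = results, assignments = assignments,
              exclusion_flow = exclusion_flow, thresholds = thresholds_used,
              manifest = manifest, truth = truth)
  if (!is.null(config$output_dir)) write_pipeline_outputs(out, config$output_dir)
  out
}

# Delimited output bundle: analysis cohort, the three table analogs,
# exclusion flow and the manifest.
write_pipeline_outputs <- function(out, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  data.table::fwrite(out$cohort, file.path(dir, "cohort.csv"))
  data.table::fwrite(out$exclusion_flow, file.path(dir, "exclusion_flow.csv"))

  cells <- out$results$cells
  data.table::fwrite(cells, file.path(dir, "table2_cells.csv"))

  prev <- data.table::rbindlist(lapply(STRATA, function(s) {
    p <- out$results[[s]]$prevalence
    if (is.null(p)) return(NULL)
    data.table::data.table(stratum = s, p)
  }))
  if (nrow(prev)) data.table::fwrite(prev, file.path(dir, "table2_prevalence.csv"))

  ors <- data.table::rbindlist(lapply(STRATA, function(s) {
    res <- out$results[[s]]
    if (is.null(res)) return(NULL)
    biv <- data.table::rbindlist(lapply(names(res$odds_ratios), function(g) {
      o <- res$odds_ratios[[g]]
      data.table::data.table(stratum = s, group = g, model = "bivariable",
                             or = o$or, ci_low = o$ci_low, ci_high = o$ci_high)
    }))
    adj <- data.table::rbindlist(lapply(names(res$fits), function(mm) {
      f <- res$fits[[mm]]
      if (is.null(f)) return(NULL)
      tt <- fit_terms(f, "^group")
      data.table::data.table(stratum = s, group = sub("^group", "", tt$term),
                             model = mm, or = tt$or, ci_low = tt$ci_low,
                             ci_high = tt$ci_high)
    }))
    rbind(biv, adj)
  }))
  if (nrow(ors)) data.table::fwrite(ors, file.path(dir, "table3_odds_ratios.csv"))

  jsonlite::write_json(out$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}
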