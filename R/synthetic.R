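# Synthetic encounter-level EHR generator.
#
# Emits the three tables the pipeline consumes (patients, encounters,
# diagnoses) plus a per-patient truth table, in two modes:
#
#  * fixture:    exact configured cell counts per stratum x exposure group x
#                outcome, built so that the full pipeline recovers the cells
#                with zero error;
#  * stochastic: outcomes drawn from a logistic model with configured
#                intercept and log-odds effects.
#
# Construction notes. Cases carry their visit history strictly inside the
# 5-year lookback of their (uniformly drawn) self-harm index date, so the
# pipeline's case index equals the generation index exactly. Non-cases get
# a *stationary* regular visit grid spanning the study window plus a
# 5-year margin, with exposure codes re-attached at sub-year cadence:
# whichever admissible encounter the pipeline draws as the matched index
# date, the classified stratum and exposure group are the same. Visits are
# distinct (patient, date) pairs; multi-diagnosis visits emit several
# diagnosis rows against one encounter row. Diagnosis coding system follows
# the encounter date (ICD-9-CM before 2015-10-01, ICD-10 after).

ICD10_TRANSITION <- as.Date("2015-10-01")

# Visit-count bands per utilization stratum over the 5-year lookback,
# chosen strictly inside the thresholds (<=33 / 34-78 / >=79 distinct
# dates, i.e. 6.6 and 15.6 visits per year) so that the +/-1 count jitter
# of a regular grid can never cross a band edge.
VISIT_BANDS <- list(LOW = c(4L, 31L), MEDIUM = c(36L, 76L), HIGH = c(81L, 140L))

# Grid steps (days) whose 5-year window counts fall inside a band for both
# 1826- and 1827-day lookbacks.
valid_grid_steps <- function(band) {
  g <- 12:600
  cnt1 <- 1826L %/% g
  cnt2 <- 1827L %/% g
  g[cnt1 >= band[1L] & cnt1 <= band[2L] & cnt2 >= band[1L] & cnt2 <= band[2L]]
}

#' Default covariate category margins
#'
#' Marginal category probabilities used when sampling synthetic patient
#' covariates, emulating the composition of a large veteran user
#' population (93% male; about three quarters White; half aged 45-69; a
#' third service-connected at 50% or more).
#'
#' @return named list of probability vectors.
#' @export
default_covariate_margins <- function() {
  list(
    age_band = c("<30" = 0.048, "30-44" = 0.124, "45-69" = 0.496, ">=70" = 0.332),
    sex = c(M = 0.931, F = 0.069),
    race = c(White = 0.7674, Black = 0.1585, Asian = 0.0098, AIAN = 0.0084,
             NHPI = 0.0096, Other = 0.0463),
    ethnicity = c(Hispanic = 0.056, NotHispanic = 0.944),
    marital = c(Single = 0.123, Married = 0.551, Widowed = 0.078,
                Divorced = 0.243, Unknown = 0.005),
    sc_band = c(None = 0.452, "<50" = 0.202, ">=50" = 0.346)
  )
}

#' Printed-table cell counts
#'
#' The stratum x exposure group x outcome cell counts of the reference
#' cohort, optionally scaled (counts rounded to integers).
#'
#' @param scale multiplicative factor applied to every cell.
#' @return data.table with `stratum`, `group`, `self_harm`, `n`.
#' @export
table2_cell_counts <- function(scale = 1) {
  path <- system.file("extdata", "table2_counts.csv", package = "ishcohort", mustWork = TRUE)
  dt <- data.table::fread(path)
  dt[, n := as.integer(round(n * scale))]
  dt[]
}

#' Build a generator configuration
#'
#' @param mode `"fixture"` (exact cell counts) or `"stochastic"` (logit
#'   outcome model).
#' @param window_start,window_end study window (default 2008-01-01 to
#'   2017-12-31).
#' @param cell_counts fixture mode: data.frame with `stratum`, `group`,
#'   `self_harm` (0/1) and `n`.
#' @param n stochastic mode: number of patients.
#' @param stratum_probs stochastic mode: P(stratum), default roughly
#'   50/25/25.
#' @param group_probs stochastic mode: P(exposure group).
#' @param logit_params stochastic mode: list with `intercept`, `group`
#'   (named log-odds vs NEITHER) and optional `covars` (named list of named
#'   log-odds per level).
#' @param covariate_margins category probabilities per covariate.
#' @param visit_bands per-stratum 5-year visit-count ranges.
#' @param cci_plant_prob probability a patient carries planted Charlson
#'   codes (alternating a weight-1 and a weight-6 condition).
#' @param seed integer seed; generation is deterministic given the config.
#' @return a validated `generator_config`.
#' @export
generator_config <- function(mode = c("fixture", "stochastic"),
                             window_start = as.Date("2008-01-01"),
                             window_end = as.Date("2017-12-31"),
                             cell_counts = NULL,
                             n = NULL,
                             stratum_probs = c(LOW = 0.4972, MEDIUM = 0.2509, HIGH = 0.2519),
                             group_probs = c(NEITHER = 0.8373, TBI_ONLY = 0.0140,
                                             PTSD_ONLY = 0.1334, COMORBID = 0.0153),
                             logit_params = NULL,
                             covariate_margins = default_covariate_margins(),
                             visit_bands = VISIT_BANDS,
                             cci_plant_prob = 0.05,
                             seed = 1L) {
  mode <- match.arg(mode)
  window_start <- as.Date(window_start); window_end <- as.Date(window_end)
  if (!(window_start < window_end)) stopf("window_start must precede window_end")
  if (mode == "fixture") {
    if (is.null(cell_counts)) stopf("fixture mode requires cell_counts")
    cc <- data.table::as.data.table(cell_counts)
    # YAML 1.1 parses a bare `n` key as a boolean; take it back
    if ("FALSE" %in% names(cc) && !"n" %in% names(cc)) {
      data.table::setnames(cc, "FALSE", "n")
    }
    need <- c("stratum", "group", "self_harm", "n")
    if (!all(need %in% names(cc))) stopf("cell_counts needs columns %s", paste(need, collapse = ", "))
    if (any(cc$n < 0)) stopf("cell counts must be non-negative")
    if (!all(cc$stratum %in% STRATA)) stopf("unknown stratum in cell_counts")
    if (!all(cc$group %in% EXPOSURE_GROUPS)) stopf("unknown exposure group in cell_counts")
    cell_counts <- cc
  } else {
    if (is.null(logit_params)) stopf("stochastic mode requires logit_params")
    if (is.null(n)) stopf("stochastic mode requires n")
    stopifnot(is.numeric(logit_params$intercept))
  }
  for (nm in names(covariate_margins)) {
    p <- covariate_margins[[nm]]
    if (any(p < 0) || abs(sum(p) - 1) > 1e-6) {
      stopf("covariate margins for '%s' must be non-negative and sum to 1", nm)
    }
  }
  for (s in names(visit_bands)) {
    b <- visit_bands[[s]]
    if (b[1L] < 2L) stopf("visit band for %s allows fewer than 2 lookback visits", s)
    if (b[1L] > b[2L]) stopf("visit band for %s is reversed", s)
    if (b[2L] > 1826L) stopf("visit band for %s exceeds the days available in a 5-year lookback", s)
    if (s %in% c("LOW", "MEDIUM", "HIGH") && length(valid_grid_steps(b)) == 0L) {
      stopf("visit band for %s admits no stationary grid step; widen the band", s)
    }
  }
  structure(list(mode = mode, window_start = window_start, window_end = window_end,
                 cell_counts = cell_counts, n = n, stratum_probs = stratum_probs,
                 group_probs = group_probs, logit_params = logit_params,
                 covariate_margins = covariate_margins, visit_bands = visit_bands,
                 cci_plant_prob = cci_plant_prob, seed = as.integer(seed)),
            class = "generator_config")
}

sample_margin <- function(n, probs) {
  names(probs)[sample.int(length(probs), n, replace = TRUE, prob = probs)]
}

# Log-odds of outcome per patient from a logit parameter list.
linear_predictor <- function(design, logit_params) {
  lp <- rep(logit_params$intercept, nrow(design))
  ge <- logit_params$group %||% numeric(0)
  hit <- match(design$group, names(ge))
  lp <- lp + ifelse(is.na(hit), 0, ge[hit])
  for (cv in names(logit_params$covars %||% list())) {
    eff <- logit_params$covars[[cv]]
    hit <- match(design[[cv]], names(eff))
    lp <- lp + ifelse(is.na(hit), 0, eff[hit])
  }
  lp
}

#' Draw outcomes from a logistic model
#'
#' P(outcome) is the inverse logit of intercept + group effect + covariate
#' effects, per patient.
#'
#' @param design data.frame with a `group` column and any covariate
#'   columns named in the parameters.
#' @param logit_params see [generator_config()].
#' @return list with `p` (probabilities) and `outcome` (0/1 draws, using
#'   the current RNG stream).
#' @export
simulate_outcomes <- function(design, logit_params) {
  lp <- linear_predictor(design, logit_params)
  if (any(!is.finite(lp))) stopf("non-finite linear predictor in outcome model")
  p <- stats::plogis(lp)
  list(p = p, outcome = stats::rbinom(length(p), 1L, p))
}

# Truth table: one row per patient with stratum, group, outcome, index
# date and visit-schedule parameters.
build_truth <- function(config) {
  w0 <- as.integer(config$window_start)
  w1 <- as.integer(config$window_end)
  if (config$mode == "fixture") {
    cc <- config$cell_counts[n > 0]
    truth <- cc[, .(stratum = rep(stratum, n), group = rep(group, n),
                    outcome = rep(self_harm, n))]
  } else {
    n <- config$n
    truth <- data.table::data.table(
      stratum = sample_margin(n, config$stratum_probs),
      group = sample_margin(n, config$group_probs)
    )
  }
  truth[, patient_id := seq_len(.N)]
  # covariates from the configured margins
  m <- config$covariate_margins
  for (nm in names(m)) truth[, (nm) := sample_margin(.N, m[[nm]])]
  truth[, index_date := as.Date(sample(w0:w1, .N, replace = TRUE), origin = "1970-01-01")]
  if (config$mode == "stochastic") {
    sim <- simulate_outcomes(truth, config$logit_params)
    truth[, outcome := sim$outcome]
  }
  # visit schedule: target count for cases, grid step for non-cases
  truth[, visits := NA_integer_]
  truth[, grid_step := NA_integer_]
  for (s in names(config$visit_bands)) {
    b <- config$visit_bands[[s]]
    idx <- which(truth$stratum == s & truth$outcome == 1L)
    if (length(idx)) {
      data.table::set(truth, i = idx, j = "visits",
                      value = sample(b[1L]:b[2L], length(idx), replace = TRUE))
    }
    gs <- valid_grid_steps(b)
    idx <- which(truth$stratum == s & truth$outcome == 0L)
    if (length(idx)) {
      data.table::set(truth, i = idx, j = "grid_step",
                      value = gs[sample.int(length(gs), length(idx), replace = TRUE)])
    }
  }
  # planted Charlson conditions, alternating weight 1 / weight 6
  truth[, cci_role := "none"]
  planted <- stats::runif(nrow(truth)) < config$cci_plant_prob
  truth[planted, cci_role := rep_len(c("cci_mild", "cci_meta"), sum(planted))]
  # self-harm condition rotates A/B/C among outcome patients
  truth[, condition := NA_character_]
  truth[outcome == 1L, condition := rep_len(c("A", "B", "C"), sum(truth$outcome == 1L))]
  truth[]
}

# Diagnosis codes per role, by coding era.
role_codes <- function(role, icd9) {
  codes <- if (icd9) {
    switch(role,
           tbi = "854.00", ptsd = "309.81",
           cci_mild = "410.90", cci_meta = "197.0",
           shA = "E950.0", shB = c("V62.84", "873.42"), shC = c("879.2", "296.20"))
  } else {
    switch(role,
           tbi = "S06.0X0A", ptsd = "F43.10",
           cci_mild = "I21.9", cci_meta = "C78.00",
           shA = "T14.91", shB = c("R45.851", "S09.90XA"), shC = c("T39.8X1A", "F32.9"))
  }
  codes
}

# Expand coded events (patient_id, date, role) into diagnosis rows.
events_to_diagnoses <- function(events) {
  if (nrow(events) == 0L) {
    return(data.table::data.table(patient_id = integer(0), date = as.Date(character(0)),
                                  icd_code = character(0), system = character(0)))
  }
  events[, icd9 := date < ICD10_TRANSITION]
  out <- events[, .(icd_code = role_codes(role[1L], icd9[1L])),
                by = .(patient_id, date, role, icd9)]
  out[, system := data.table::fifelse(icd9, "icd9", "icd10")]
  out[, c("role", "icd9") := NULL]
  out[]
}

#' Generate synthetic patient, encounter and diagnosis tables
#'
#' @param config a [generator_config()].
#' @return list with `patients`, `encounters`, `diagnoses`, `truth` and the
#'   echoed `config`. Deterministic given `config$seed`: the same config
#'   yields byte-identical tables.
#' @export
#' @examples
#' cfg <- generator_config(
#'   mode = "fixture",
#'   cell_counts = data.frame(stratum = "HIGH", group = "COMORBID",
#'                            self_harm = 1, n = 3),
#'   seed = 7
#' )
#' dat <- generate_cohort_data(cfg)
#' nrow(dat$truth)
generate_cohort_data <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  with_seed(config$seed, {
    truth <- build_truth(config)
    cases <- truth[outcome == 1L]
    ctrls <- truth[outcome == 0L]
    w1 <- as.integer(config$window_end)

    # ---- cases: visit history strictly inside the lookback ----------------
    case_enc <- NULL
    case_events <- NULL
    if (nrow(cases)) {
      lb_len <- as.integer(cases$index_date) - as.integer(lookback_start(cases$index_date))
      offs <- lapply(seq_len(nrow(cases)), function(i) {
        sort(sample.int(lb_len[i], cases$visits[i]))  # days before index, distinct
      })
      nvis <- lengths(offs)
      case_enc <- data.table::data.table(
        patient_id = rep(cases$patient_id, nvis),
        date = as.Date(rep(as.integer(cases$index_date), nvis) - unlist(offs),
                       origin = "1970-01-01")
      )
      # index-date encounter carrying the qualifying self-harm codes
      idx_enc <- cases[, .(patient_id, date = index_date)]
      case_enc <- rbind(case_enc, idx_enc)
      # exposure codes on the two earliest lookback visits (distinct dates)
      first2 <- vapply(offs, function(o) o[length(o)], integer(1))
      second2 <- vapply(offs, function(o) o[length(o) - 1L], integer(1))
      ev <- list(
        cases[, .(patient_id, date = index_date, role = paste0("sh", condition))]
      )
      has_tbi <- cases$group %in% c("TBI_ONLY", "COMORBID")
      has_ptsd <- cases$group %in% c("PTSD_ONLY", "COMORBID")
      ev[[length(ev) + 1L]] <- data.table::data.table(
        patient_id = cases$patient_id[has_tbi],
        date = as.Date(as.integer(cases$index_date[has_tbi]) - first2[has_tbi],
                       origin = "1970-01-01"),
        role = "tbi")
      ev[[length(ev) + 1L]] <- data.table::data.table(
        patient_id = cases$patient_id[has_ptsd],
        date = as.Date(as.integer(cases$index_date[has_ptsd]) - second2[has_ptsd],
                       origin = "1970-01-01"),
        role = "ptsd")
      has_cci <- cases$cci_role != "none"
      third2 <- vapply(offs, function(o) o[max(1L, length(o) - 2L)], integer(1))
      ev[[length(ev) + 1L]] <- data.table::data.table(
        patient_id = cases$patient_id[has_cci],
        date = as.Date(as.integer(cases$index_date[has_cci]) - third2[has_cci],
                       origin = "1970-01-01"),
        role = cases$cci_role[has_cci])
      case_events <- data.table::rbindlist(ev)
    }

    # ---- non-cases: stationary visit grid ---------------------------------
    ctrl_enc <- NULL
    ctrl_events <- NULL
    if (nrow(ctrls)) {
      g <- ctrls$grid_step
      anchor <- as.integer(config$window_start) - 2007L +
        (sample.int(10000L, nrow(ctrls), replace = TRUE) %% g)
      npts <- (w1 - anchor) %/% g + 1L
      ctrl_expand <- data.table::data.table(
        patient_id = rep(ctrls$patient_id, npts),
        date_int = rep(anchor, npts) + (sequence(npts) - 1L) * rep(g, npts),
        idx = sequence(npts),
        kprime = rep(pmax(1L, 750L %/% g), npts),
        group = rep(ctrls$group, npts),
        cci_role = rep(ctrls$cci_role, npts)
      )
      ctrl_enc <- ctrl_expand[, .(patient_id, date = as.Date(date_int, origin = "1970-01-01"))]
      two_k <- 2L * ctrl_expand$kprime
      tbi_slot <- ctrl_expand$idx %% two_k == 1L
      ptsd_slot <- ctrl_expand$idx %% two_k == (1L + ctrl_expand$kprime) %% two_k
      ev <- list(
        ctrl_expand[tbi_slot & group %in% c("TBI_ONLY", "COMORBID"),
                    .(patient_id, date = as.Date(date_int, origin = "1970-01-01"), role = "tbi")],
        ctrl_expand[ptsd_slot & group %in% c("PTSD_ONLY", "COMORBID"),
                    .(patient_id, date = as.Date(date_int, origin = "1970-01-01"), role = "ptsd")],
        ctrl_expand[tbi_slot & cci_role != "none",
                    .(patient_id, date = as.Date(date_int, origin = "1970-01-01"), role = cci_role)]
      )
      ctrl_events <- data.table::rbindlist(ev)
    }

    encounters <- data.table::rbindlist(list(case_enc, ctrl_enc), use.names = TRUE)
    data.table::setorder(encounters, patient_id, date)
    encounters[, encounter_id := seq_len(.N)]
    encounters[, setting := data.table::fifelse(stats::runif(.N) < 0.05, "inpatient", "outpatient")]
    data.table::setcolorder(encounters, c("encounter_id", "patient_id", "date", "setting"))

    events <- data.table::rbindlist(list(case_events, ctrl_events), use.names = TRUE)
    diagnoses <- events_to_diagnoses(events)
    diagnoses <- encounters[, .(encounter_id, patient_id, date)][
      diagnoses, on = c("patient_id", "date")]
    if (anyNA(diagnoses$encounter_id)) stopf("internal: coded event without an encounter")
    diagnoses <- diagnoses[, .(encounter_id, icd_code, system)]
    data.table::setorder(diagnoses, encounter_id, icd_code)

    patients <- build_patients(truth)
    list(patients = patients, encounters = encounters, diagnoses = diagnoses,
         truth = truth, config = config)
  })
}

# Patient demographics consistent with the truth table's covariate bins at
# the generation index date.
build_patients <- function(truth) {
  age_lo <- c("<30" = 20L, "30-44" = 30L, "45-69" = 45L, ">=70" = 70L)
  age_hi <- c("<30" = 29L, "30-44" = 44L, "45-69" = 69L, ">=70" = 89L)
  n <- nrow(truth)
  yrs <- age_lo[truth$age_band] +
    floor(stats::runif(n) * (age_hi[truth$age_band] - age_lo[truth$age_band] + 1L))
  extra_days <- floor(stats::runif(n) * 330)
  birth <- as.Date(as.integer(truth$index_date) - as.integer(yrs * 365.25) - extra_days,
                   origin = "1970-01-01")
  sc <- rep(NA_real_, n)
  lt50 <- truth$sc_band == "<50"
  ge50 <- truth$sc_band == ">=50"
  sc[lt50] <- sample(c(10, 20, 30, 40), sum(lt50), replace = TRUE)
  sc[ge50] <- sample(seq(50, 100, by = 10), sum(ge50), replace = TRUE)
  data.table::data.table(
    patient_id = truth$patient_id, birth_date = birth, sex = truth$sex,
    race = truth$race, ethnicity = truth$ethnicity, marital = truth$marital,
    service_connection = sc
  )
}

#' Write a generated data set to delimited files
#'
#' Writes patients/encounters/diagnoses/truth as CSV plus a JSON manifest
#' echoing the seed and configuration.
#'
#' @param dat output of [generate_cohort_data()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort_data <- function(dat, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in c("patients", "encounters", "diagnoses", "truth")) {
    data.table::fwrite(dat[[nm]], file.path(dir, paste0(nm, ".csv")))
  }
  cfg <- dat$config
  manifest <- list(
    seed = cfg$seed, mode = cfg$mode,
    window = c(as.character(cfg$window_start), as.character(cfg$window_end)),
    n_patients = nrow(dat$patients), n_encounters = nrow(dat$encounters),
    n_diagnoses = nrow(dat$diagnoses)
  )
  jsonlite::write_json(manifest, file.path(dir, "generator_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
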