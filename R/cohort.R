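# Cohort construction: index-date assignment, eligibility, utilization
# strata and the analysis table.

AGE_BANDS <- c("<30", "30-44", "45-69", ">=70")
RACE_LEVELS <- c("White", "Black", "Asian", "AIAN", "NHPI", "Other")
ETHNICITY_LEVELS <- c("Hispanic", "NotHispanic")
MARITAL_LEVELS <- c("Single", "Married", "Widowed", "Divorced", "Unknown")
SC_LEVELS <- c("None", "<50", ">=50")
STRATA <- c("LOW", "MEDIUM", "HIGH")

#' Assign index dates to cases and distribution-matched controls
#'
#' Cases receive the date of their first self-harm encounter. Each control
#' receives a date drawn from their own encounters so that the calendar
#' distribution of control index dates matches the empirical distribution
#' of case index dates: a calendar bin (months, width `bin_width`) is
#' sampled from the case-index distribution, then one of the control's
#' encounter dates inside that bin is drawn uniformly; a control with no
#' encounter in the sampled bin falls back to their nearest bin containing
#' an encounter (ties broken toward the earlier bin). With no cases at all,
#' controls are sampled uniformly over their own encounters.
#'
#' @param case_index data.frame with `patient_id`, `index_date` (cases).
#' @param control_encounters data.frame with `patient_id`, `date`: the
#'   candidate (in-window) encounters of non-case patients.
#' @param bin_width calendar bin width in months (default 1).
#' @param seed integer seed; assignment is reproducible given the seed.
#' @return data.table with `patient_id`, `index_date`, `is_case`, `source`
#'   (`first_event`/`matched_random`) and `sampling_bin` (label of the bin
#'   the index was drawn from; `NA` for cases). Controls without any
#'   candidate encounter are excluded and counted in the `exclusions`
#'   attribute.
#' @export
assign_index_dates <- function(case_index, control_encounters, bin_width = 1L, seed = 1L) {
  cases <- data.table::as.data.table(case_index)
  ctrl <- data.table::as.data.table(control_encounters)
  ctrl <- ctrl[!patient_id %in% cases$patient_id]
  out_cases <- cases[, .(patient_id, index_date = as.Date(index_date),
                         is_case = TRUE, source = "first_event",
                         sampling_bin = NA_character_)]
  ctrl_ids <- unique(ctrl$patient_id)
  n_ctrl <- length(ctrl_ids)
  if (n_ctrl == 0L) {
    res <- out_cases
    data.table::setattr(res, "exclusions",
                        data.table::data.table(reason = "control_without_encounters", n = 0L))
    return(res[])
  }
  ctrl[, date := as.Date(date)]
  ctrl[, bin := month_index(date) %/% as.integer(bin_width)]
  data.table::setorder(ctrl, patient_id, date)

  uniform_mode <- nrow(cases) == 0L
  res_ctrl <- with_seed(seed, {
    if (uniform_mode) {
      message("no cases present; control index dates sampled uniformly over own encounters")
      picks <- ctrl[, .SD[sample.int(.N, 1L)], by = patient_id]
      picks[, .(patient_id, index_date = date, chosen_bin = bin)]
    } else {
      case_bins <- month_index(as.Date(cases$index_date)) %/% as.integer(bin_width)
      bin_tab <- table(case_bins)
      bins <- as.integer(names(bin_tab))
      probs <- as.numeric(bin_tab) / sum(bin_tab)
      # one sampled target bin per control, in sorted patient order
      target <- data.table::data.table(
        patient_id = sort(ctrl_ids),
        target_bin = bins[sample.int(length(bins), n_ctrl, replace = TRUE, prob = probs)]
      )
      # nearest candidate bin per control (ties -> earlier bin)
      cand <- unique(ctrl[, .(patient_id, bin)])
      cand <- cand[target, on = "patient_id"]
      cand[, dist := abs(bin - target_bin)]
      data.table::setorder(cand, patient_id, dist, bin)
      chosen <- cand[, .(chosen_bin = bin[1L], target_bin = target_bin[1L]),
                     by = patient_id]
      # uniform draw among the control's encounter dates inside the chosen bin
      pool <- ctrl[chosen, on = .(patient_id, bin = chosen_bin),
                   .(patient_id, date, target_bin), nomatch = NULL]
      data.table::setorder(pool, patient_id, date)
      u <- stats::runif(n_ctrl)
      pool[, u_i := u[.GRP], by = patient_id]
      picks <- pool[, .(index_date = date[ceiling(u_i[1L] * .N)],
                        chosen_bin = month_index(date[1L]) %/% as.integer(bin_width)),
                    by = patient_id]
      picks
    }
  })
  res_ctrl <- res_ctrl[, .(patient_id, index_date,
                           is_case = FALSE, source = "matched_random",
                           sampling_bin = as.character(chosen_bin))]
  res <- data.table::rbindlist(list(out_cases, res_ctrl))
  data.table::setorder(res, patient_id)
  data.table::setattr(res, "exclusions",
                      data.table::data.table(reason = "control_without_encounters",
                                             n = 0L))
  res[]
}

#' Apply the eligibility rule
#'
#' Keeps veterans with at least `min_visits` distinct encounter dates in
#' the half-open 5-year lookback `[index - 5y, index)`. A visit exactly at
#' `index - 5y` counts; a visit on the index date does not.
#'
#' @param encounters data.frame with `patient_id`, `date`.
#' @param assignments output of [assign_index_dates()].
#' @param min_visits minimum distinct lookback visit dates (default 2).
#' @param lookback_years lookback length in calendar years (default 5).
#' @return data.table of eligible assignments (same columns), with an
#'   `exclusions` attribute counting patients removed per reason.
#' @export
apply_eligibility <- function(encounters, assignments, min_visits = 2L,
                              lookback_years = 5L) {
  asg <- data.table::as.data.table(assignments)
  counts <- lookback_visit_counts(encounters, asg, lookback_years)
  keep <- counts[visits >= min_visits, patient_id]
  out <- asg[patient_id %in% keep]
  excl <- data.table::data.table(
    reason = sprintf("fewer_than_%d_lookback_visits", min_visits),
    n = nrow(asg) - nrow(out)
  )
  data.table::setattr(out, "exclusions", excl)
  out[]
}

# Distinct encounter dates per patient inside [index - lookback, index).
lookback_visit_counts <- function(encounters, assignments, lookback_years = 5L) {
  enc <- data.table::as.data.table(encounters)[, .(patient_id, date = as.Date(date))]
  asg <- data.table::as.data.table(assignments)[, .(patient_id, index_date)]
  asg[, lb_start := lookback_start(index_date, lookback_years)]
  j <- enc[asg, on = "patient_id", nomatch = NULL, allow.cartesian = TRUE]
  j <- j[date >= lb_start & date < index_date]
  got <- j[, .(visits = data.table::uniqueN(date)), by = patient_id]
  out <- got[asg[, .(patient_id)], on = "patient_id"]
  out[is.na(visits), visits := 0L]
  out[]
}

#' Utilization strata from lookback visit counts
#'
#' Average yearly visits are distinct lookback encounter dates divided by
#' the lookback length in years. Strata follow the at-or-below convention:
#' LOW when yearly visits are at or below the lower threshold, MEDIUM when
#' above it but at or below the upper threshold, HIGH above that. Default
#' thresholds are 6.6 and 15.6 visits per year (the 50th and 75th
#' percentile cut points of the reference cohort); passing
#' `thresholds = "empirical"` recomputes them as the 50th/75th empirical
#' percentiles of the eligible cohort itself.
#'
#' @param encounters data.frame with `patient_id`, `date`.
#' @param assignments eligible assignments ([apply_eligibility()]).
#' @param thresholds numeric length-2 `c(p50, p75)` or `"empirical"`.
#' @param lookback_years lookback length in years.
#' @return data.table with `patient_id`, `yearly_visits`, `stratum`, and a
#'   `thresholds` attribute holding the thresholds used.
#' @export
compute_utilization <- function(encounters, assignments,
                                thresholds = c(6.6, 15.6), lookback_years = 5L) {
  counts <- lookback_visit_counts(encounters, assignments, lookback_years)
  counts[, yearly_visits := visits / lookback_years]
  if (identical(thresholds, "empirical")) {
    thresholds <- unname(stats::quantile(counts$yearly_visits, c(0.5, 0.75), type = 1))
  }
  stopifnot(is.numeric(thresholds), length(thresholds) == 2L,
            thresholds[1L] <= thresholds[2L])
  counts[, stratum := utilization_stratum(yearly_visits, thresholds)]
  out <- counts[, .(patient_id, yearly_visits, stratum)]
  data.table::setattr(out, "thresholds", thresholds)
  out[]
}

#' @rdname compute_utilization
#' @param yearly_visits numeric vector of average yearly visit counts.
#' @export
utilization_stratum <- function(yearly_visits, thresholds = c(6.6, 15.6)) {
  data.table::fcase(
    yearly_visits <= thresholds[1L], "LOW",
    yearly_visits <= thresholds[2L], "MEDIUM",
    default = "HIGH"
  )
}

# Map raw covariate values onto the declared level sets; unmappable values
# go to the declared catch-all (marital Unknown, race Other).
bin_age <- function(age) {
  data.table::fcase(age < 30, "<30", age <= 44, "30-44", age <= 69, "45-69",
                    default = ">=70")
}
bin_service_connection <- function(pct) {
  data.table::fcase(is.na(pct), "None", pct < 50, "<50", default = ">=50")
}

#' Assemble the analysis table
#'
#' One row per eligible veteran: utilization stratum, exposure group from
#' the 5-year lookback, outcome, and covariates binned at the index date
#' (age <30 / 30-44 / 45-69 / >=70; service connection None / <50 / >=50;
#' marital status with an explicit Unknown level; race with an Other
#' catch-all). Counts of values routed to catch-all levels are recorded in
#' the `recoded` attribute.
#'
#' @param patients data.frame with `patient_id`, `birth_date`, `sex`,
#'   `race`, `ethnicity`, `marital`, `service_connection` (percent, `NA`
#'   for none).
#' @param encounters data.frame with `encounter_id`, `patient_id`, `date`.
#' @param diagnoses data.frame with `encounter_id`, `icd_code`, `system`.
#' @param assignments eligible index assignments.
#' @param utilization output of [compute_utilization()].
#' @param registry a `codeset_registry`.
#' @param cci_map a `cci_map`; Charlson scores use lookback diagnoses.
#' @param lookback_years lookback length in years.
#' @return data.table, one row per eligible veteran.
#' @export
build_cohort_table <- function(patients, encounters, diagnoses, assignments,
                               utilization, registry, cci_map,
                               lookback_years = 5L) {
  pat <- data.table::as.data.table(patients)
  enc <- data.table::as.data.table(encounters)[, .(encounter_id, patient_id, date = as.Date(date))]
  diag <- data.table::as.data.table(diagnoses)
  asg <- data.table::as.data.table(assignments)

  windows <- asg[, .(patient_id, start = lookback_start(index_date, lookback_years),
                     end = index_date)]

  dated <- diag[enc, on = "encounter_id", nomatch = NULL,
                .(patient_id, date, icd_code, system)]
  expo <- exposure_groups_bulk(dated, windows, registry)

  # Charlson from lookback diagnoses
  lb <- dated[windows, on = "patient_id", nomatch = NULL, allow.cartesian = TRUE]
  lb <- lb[date >= start & date < end,
           .(patient_id, system = tolower(system), code = normalize_code(icd_code))]
  cci <- cci_score_bulk(lb, cci_map)
  cci_all <- cci[asg[, .(patient_id)], on = "patient_id"]
  cci_all[is.na(score), `:=`(score = 0L, band = "LOW")]

  out <- asg[, .(patient_id, index_date, outcome = as.integer(is_case))]
  out <- pat[out, on = "patient_id"]
  out[, age := age_at(as.Date(birth_date), index_date)]
  out[, age_band := bin_age(age)]
  out[, sex := data.table::fifelse(toupper(substr(sex, 1L, 1L)) == "F", "F", "M")]

  n_race_other <- sum(!out$race %in% RACE_LEVELS)
  out[!race %in% RACE_LEVELS, race := "Other"]
  out[, ethnicity := data.table::fifelse(ethnicity %in% "Hispanic", "Hispanic", "NotHispanic")]
  n_marital_unknown <- sum(is.na(out$marital) | !out$marital %in% setdiff(MARITAL_LEVELS, "Unknown"))
  out[is.na(marital) | !marital %in% MARITAL_LEVELS, marital := "Unknown"]
  out[, sc_band := bin_service_connection(service_connection)]

  out <- data.table::as.data.table(utilization)[out, on = "patient_id"]
  out <- expo[, .(patient_id, group)][out, on = "patient_id"]
  out <- cci_all[, .(patient_id, cci_score = score, cci_band = band)][out, on = "patient_id"]

  res <- out[, .(patient_id, index_date, stratum, group, outcome,
                 age_band, sex, race, ethnicity, marital, sc_band,
                 cci_score, cci_band, yearly_visits)]
  data.table::setattr(res, "recoded",
                      data.table::data.table(
                        field = c("race_to_other", "marital_to_unknown"),
                        n = c(n_race_other, n_marital_unknown)))
  res[]
}
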