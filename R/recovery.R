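# Parameter-recovery simulations: plant known exposure log-odds in
# synthetic cohorts and check that the fitted models' Wald intervals
# recover them at close to nominal coverage.

#' Default parameters for the recovery simulations
#'
#' `bivariable`: exposure groups at the reference cohort margins, a rare
#' baseline (1.9% outcome among the unexposed, the high-utilization
#' reference prevalence) and planted bivariable log-odds ln(2.81) /
#' ln(3.21) / ln(6.72) for TBI only / PTSD only / comorbid.
#'
#' `full`: planted adjusted log-odds ln(2.44) / ln(2.90) / ln(4.26) with
#' genuine confounding: exposure-group probabilities depend on age band,
#' and age (with the other covariates) also shifts the outcome, so the
#' crude comorbid OR is biased away from the planted value and only the
#' adjusted model should recover it.
#'
#' @param model `"bivariable"` or `"full"`.
#' @return parameter list for [simulate_cohort_rows()].
#' @export
recovery_params <- function(model = c("bivariable", "full")) {
  model <- match.arg(model)
  margins <- default_covariate_margins()
  margins$cci_band <- c(LOW = 0.80, MEDIUM = 0.18, HIGH = 0.02)
  if (model == "bivariable") {
    list(
      margins = margins,
      group_probs = c(NEITHER = 0.8373, TBI_ONLY = 0.0140,
                      PTSD_ONLY = 0.1334, COMORBID = 0.0153),
      logit = list(
        intercept = stats::qlogis(0.019),
        group = c(TBI_ONLY = log(2.81), PTSD_ONLY = log(3.21), COMORBID = log(6.72))
      )
    )
  } else {
    group_by_age <- rbind(
      "<30"   = c(NEITHER = 0.700, TBI_ONLY = 0.030, PTSD_ONLY = 0.210, COMORBID = 0.060),
      "30-44" = c(NEITHER = 0.760, TBI_ONLY = 0.020, PTSD_ONLY = 0.170, COMORBID = 0.050),
      "45-69" = c(NEITHER = 0.840, TBI_ONLY = 0.013, PTSD_ONLY = 0.135, COMORBID = 0.012),
      ">=70"  = c(NEITHER = 0.950, TBI_ONLY = 0.005, PTSD_ONLY = 0.043, COMORBID = 0.002)
    )
    list(
      margins = margins,
      group_probs = group_by_age,
      logit = list(
        intercept = stats::qlogis(0.019),
        group = c(TBI_ONLY = log(2.44), PTSD_ONLY = log(2.90), COMORBID = log(4.26)),
        covars = list(
          age_band = c("<30" = 1.4, "30-44" = 0.8, ">=70" = -1.4),
          sex = c(F = 0.4),
          race = c(Black = -0.05, Other = -0.10),
          ethnicity = c(Hispanic = 0.05),
          marital = c(Single = 0.4, Divorced = 0.5, Widowed = 0.2),
          sc_band = c(">=50" = 0.3),
          cci_band = c(MEDIUM = -0.3, HIGH = -0.3)
        )
      )
    )
  }
}

#' Simulate analysis-ready cohort rows from a logit model
#'
#' Draws covariates from category margins, the exposure group from either
#' a probability vector or an age-band-conditional probability matrix (the
#' confounded design), and the outcome from the logistic model.
#'
#' @param n number of rows.
#' @param params list with `margins`, `group_probs`, `logit` (see
#'   [recovery_params()]).
#' @return data.table shaped like a single-stratum cohort table.
#' @export
simulate_cohort_rows <- function(n, params) {
  dt <- data.table::data.table(patient_id = seq_len(n))
  for (nm in names(params$margins)) {
    dt[, (nm) := sample_margin(n, params$margins[[nm]])]
  }
  gp <- params$group_probs
  if (is.matrix(gp)) {
    dt[, group := NA_character_]
    for (ab in rownames(gp)) {
      idx <- which(dt$age_band == ab)
      if (length(idx)) {
        data.table::set(dt, i = idx, j = "group",
                        value = sample_margin(length(idx), gp[ab, ]))
      }
    }
  } else {
    dt[, group := sample_margin(n, gp)]
  }
  sim <- simulate_outcomes(dt, params$logit)
  dt[, outcome := sim$outcome]
  dt[]
}

#' Planted-effect recovery across replicate simulations
#'
#' For each replicate, simulates a cohort of `n` rows with the planted
#' exposure log-odds, fits the matching model (bivariable: exposure group
#' only; full: exposure group plus all covariates) and records whether the
#' Wald 95% interval for the comorbid term covers the planted value.
#'
#' @param model `"bivariable"` or `"full"`.
#' @param n rows per replicate.
#' @param reps number of replicates.
#' @param seed integer seed (one stream per replicate, derived).
#' @param params parameter list, defaulting to [recovery_params()].
#' @return data.table with one row per replicate (`estimate`, `ci_low`,
#'   `ci_high`, `covered`); the planted odds ratio and coverage count are
#'   in the `planted` / `coverage` attributes.
#' @export
simulate_recovery <- function(model = c("bivariable", "full"), n = 50000L,
                              reps = 100L, seed = 1L, params = recovery_params(model)) {
  model <- match.arg(model)
  planted_or <- exp(params$logit$group[["COMORBID"]])
  terms <- if (model == "bivariable") "group" else
    c("group", "age_band", "sex", "race", "ethnicity", "marital", "sc_band", "cci_band")
  # one well-scattered RNG stream per replicate
  rep_seeds <- with_seed(derive_seed(seed, paste0("recovery-", model)),
                         sample.int(.Machine$integer.max - 1L, reps))
  rows <- vector("list", reps)
  for (r in seq_len(reps)) {
    rows[[r]] <- with_seed(rep_seeds[r], {
      dat <- simulate_cohort_rows(n, params)
      fit <- suppressMessages(
        fit_logistic(dat, outcome = "outcome", terms = terms,
                     ref_levels = list(group = "NEITHER"))
      )
      co <- fit_terms(fit, "^groupCOMORBID$")
      data.table::data.table(
        rep = r, estimate = co$or, ci_low = co$ci_low, ci_high = co$ci_high,
        covered = co$ci_low <= planted_or & planted_or <= co$ci_high
      )
    })
  }
  out <- data.table::rbindlist(rows)
  data.table::setattr(out, "planted", planted_or)
  data.table::setattr(out, "coverage", sum(out$covered))
  out[]
}
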