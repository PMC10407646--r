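# Encounter-level self-harm phenotype and windowed exposure detection.
#
# An encounter is flagged as intentional self-harm when its diagnosis codes
# meet any of three conditions:
#   A  a code that explicitly indicates suicide attempt / intentional self-harm
#   B  a suicidal-ideation code AND an injury-or-poisoning code on the same
#      encounter
#   C  an injury-or-poisoning code AND a mental-disorder code on the same
#      encounter
# "Same encounter" means the same encounter record, not the same calendar
# day. A single code may serve both sides of a conjunction if it belongs to
# both sets.

SELF_HARM_CONDITIONS <- c("A_explicit", "B_ideation_plus_injury", "C_injury_plus_mental")
EXPOSURE_GROUPS <- c("NEITHER", "TBI_ONLY", "PTSD_ONLY", "COMORBID")

#' Classify a single encounter's codes against the self-harm phenotype
#'
#' @param codes character vector of the encounter's diagnosis codes.
#' @param systems coding system per code (`icd9`/`icd10`), recycled.
#' @param registry a `codeset_registry`.
#' @return character vector of satisfied conditions (subset of
#'   `A_explicit`, `B_ideation_plus_injury`, `C_injury_plus_mental`);
#'   empty when the encounter is not flagged.
#' @export
#' @examples
#' reg <- load_codesets()
#' classify_encounter(c("R45.851", "S09.90XA"), "icd10", reg)
classify_encounter <- function(codes, systems, registry) {
  if (length(codes) == 0L) return(character(0))
  dt <- data.table::data.table(
    encounter_id = 1L,
    system = rep_len(tolower(systems), length(codes)),
    code = normalize_code(codes)
  )
  flagged <- flag_encounters(dt, registry)
  if (nrow(flagged) == 0L) return(character(0))
  SELF_HARM_CONDITIONS[c(flagged$A_explicit, flagged$B_ideation_plus_injury,
                         flagged$C_injury_plus_mental)]
}

# Bulk three-condition evaluation over a diagnosis table with columns
# encounter_id, system, code (normalized). Returns only flagged encounters,
# with one logical column per condition.
flag_encounters <- function(diag_table, registry) {
  dt <- data.table::as.data.table(diag_table)
  flags <- match_codes(dt[, .(system, code)], registry,
                       sets = c("SELF_HARM_EXPLICIT", "SUICIDAL_IDEATION",
                                "INJURY_POISONING", "MENTAL_DISORDER"))
  enc <- data.table::data.table(
    encounter_id = dt$encounter_id,
    sh = flags$SELF_HARM_EXPLICIT, si = flags$SUICIDAL_IDEATION,
    ij = flags$INJURY_POISONING, md = flags$MENTAL_DISORDER
  )
  agg <- enc[, .(sh = any(sh), si = any(si), ij = any(ij), md = any(md)),
             by = encounter_id]
  agg[, `:=`(A_explicit = sh,
             B_ideation_plus_injury = si & ij,
             C_injury_plus_mental = ij & md)]
  agg[A_explicit | B_ideation_plus_injury | C_injury_plus_mental,
      .(encounter_id, A_explicit, B_ideation_plus_injury, C_injury_plus_mental)]
}

#' Flag self-harm encounters across a whole diagnosis table
#'
#' @param encounters data.frame with `encounter_id`, `patient_id`, `date`.
#' @param diagnoses data.frame with `encounter_id`, `icd_code`, `system`.
#' @param registry a `codeset_registry`.
#' @return data.table of flagged encounters with `patient_id`, `date` and a
#'   logical column per condition; suitable as an audit trail.
#' @export
classify_encounters <- function(encounters, diagnoses, registry) {
  enc <- data.table::as.data.table(encounters)
  diag <- data.table::as.data.table(diagnoses)
  if (nrow(diag) == 0L) {
    return(data.table::data.table(
      encounter_id = integer(0), patient_id = integer(0),
      date = as.Date(character(0)), A_explicit = logical(0),
      B_ideation_plus_injury = logical(0), C_injury_plus_mental = logical(0)
    ))
  }
  dt <- diag[, .(encounter_id, system = tolower(system), code = normalize_code(icd_code))]
  flagged <- flag_encounters(dt, registry)
  out <- enc[, .(encounter_id, patient_id, date)][flagged, on = "encounter_id", nomatch = NULL]
  data.table::setcolorder(out, c("encounter_id", "patient_id", "date"))
  out[]
}

#' First self-harm encounter per patient
#'
#' The earliest flagged encounter defines the case index date; encounters
#' flagged on the same date are broken by the smallest encounter ID.
#'
#' @param flagged output of [classify_encounters()].
#' @return data.table with `patient_id`, `index_date`, `encounter_id`
#'   (one row per patient with at least one flag).
#' @export
first_self_harm <- function(flagged) {
  dt <- data.table::as.data.table(flagged)
  if (nrow(dt) == 0L) {
    return(data.table::data.table(patient_id = integer(0),
                                  index_date = as.Date(character(0)),
                                  encounter_id = integer(0)))
  }
  data.table::setorder(dt, patient_id, date, encounter_id)
  dt[, .(index_date = date[1L], encounter_id = encounter_id[1L]), by = patient_id]
}

#' TBI/PTSD exposure status within a date window
#'
#' Exposure is positive when at least one matching code sits on an
#' encounter dated inside the half-open window `[start, end)`. The group is
#' the deterministic map of the two booleans into the four mutually
#' exclusive exposure groups.
#'
#' @param dated_diagnoses data.frame with `date`, `icd_code`, `system` for
#'   one patient (diagnoses joined to their encounter dates).
#' @param window length-2 `Date` vector `c(start, end)`, `start < end`.
#' @param registry a `codeset_registry`.
#' @return list with logicals `tbi`, `ptsd` and `group`.
#' @export
exposure_in_window <- function(dated_diagnoses, window, registry) {
  stopifnot(length(window) == 2L)
  window <- as.Date(window)
  if (!(window[1L] < window[2L])) stopf("exposure window must satisfy start < end")
  dt <- data.table::as.data.table(dated_diagnoses)
  dt <- dt[as.Date(date) >= window[1L] & as.Date(date) < window[2L]]
  if (nrow(dt) == 0L) {
    return(list(tbi = FALSE, ptsd = FALSE, group = "NEITHER"))
  }
  flags <- match_codes(
    dt[, .(system = tolower(system), code = normalize_code(icd_code))],
    registry, sets = c("TBI", "PTSD")
  )
  tbi <- any(flags$TBI)
  ptsd <- any(flags$PTSD)
  list(tbi = tbi, ptsd = ptsd, group = exposure_group(tbi, ptsd))
}

#' @rdname exposure_in_window
#' @param tbi,ptsd logical vectors.
#' @export
exposure_group <- function(tbi, ptsd) {
  data.table::fcase(
    tbi & ptsd, "COMORBID",
    tbi & !ptsd, "TBI_ONLY",
    !tbi & ptsd, "PTSD_ONLY",
    default = "NEITHER"
  )
}

# Bulk exposure classification: for per-patient windows (patient_id, start,
# end) and the full dated diagnosis table, returns one row per patient with
# tbi/ptsd flags and the exposure group.
exposure_groups_bulk <- function(dated_diagnoses, windows, registry) {
  win <- data.table::as.data.table(windows)
  dt <- data.table::as.data.table(dated_diagnoses)
  out <- win[, .(patient_id)]
  if (nrow(dt)) {
    flags <- match_codes(
      dt[, .(system = tolower(system), code = normalize_code(icd_code))],
      registry, sets = c("TBI", "PTSD")
    )
    rel <- dt[, .(patient_id, date)][, `:=`(tbi = flags$TBI, ptsd = flags$PTSD)]
    rel <- rel[tbi | ptsd]
    rel <- rel[win, on = "patient_id", nomatch = NULL]
    rel <- rel[date >= start & date < end]
    got <- rel[, .(tbi = any(tbi), ptsd = any(ptsd)), by = patient_id]
    out <- got[out, on = "patient_id"]
  } else {
    out[, `:=`(tbi = NA, ptsd = NA)]
  }
  out[is.na(tbi), tbi := FALSE]
  out[is.na(ptsd), ptsd := FALSE]
  out[, group := exposure_group(tbi, ptsd)]
  out[]
}
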