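# Charlson Comorbidity Index from lookback diagnoses.
#
# The mapping from ICD codes to the 17 Charlson conditions is file-driven
# like the phenotype code sets. The bundled default is a Quan-style
# administrative-claims prefix mapping with the original condition weights
# (1/2/3/6). Scores use the plain index: no age points, since age enters the
# regression models as its own covariate.

# Severe form supersedes the mild form within each pair.
CCI_HIERARCHY <- list(
  c(severe = "diabetes_complicated",          mild = "diabetes_uncomplicated"),
  c(severe = "metastatic_solid_tumor",        mild = "any_malignancy"),
  c(severe = "moderate_severe_liver_disease", mild = "mild_liver_disease")
)

#' Load a Charlson condition mapping
#'
#' Reads a delimited file with columns `condition`, `weight`, `system`
#' (`icd9`/`icd10`) and `prefix`; range tokens expand exactly as in
#' [load_codesets()].
#'
#' @param path file path; defaults to the bundled Quan-style mapping.
#' @return a `cci_map` object.
#' @export
load_cci_map <- function(path = default_cci_map_path()) {
  if (!file.exists(path)) stopf("Charlson mapping file not found: %s", path)
  raw <- data.table::fread(path, colClasses = list(character = c("condition", "system", "prefix")))
  need <- c("condition", "weight", "system", "prefix")
  if (!all(need %in% names(raw))) {
    stopf("Charlson mapping %s lacks column(s): %s", path,
          paste(setdiff(need, names(raw)), collapse = ", "))
  }
  raw[, system := tolower(trimws(system))]
  bad <- setdiff(unique(raw$system), ICD_SYSTEMS)
  if (length(bad)) stopf("unknown coding system(s): %s", paste(bad, collapse = ", "))
  raw[, weight := as.integer(weight)]
  if (any(is.na(raw$weight) | raw$weight < 0L)) stopf("Charlson weights must be non-negative integers")
  w <- unique(raw[, .(condition, weight)])
  if (anyDuplicated(w$condition)) {
    stopf("condition(s) mapped with inconsistent weights: %s",
          paste(w$condition[duplicated(w$condition)], collapse = ", "))
  }
  raw[, prefix := normalize_code(prefix)]
  entries <- raw[, .(prefix = unlist(lapply(prefix, expand_prefix_range))),
                 by = .(condition, weight, system)]
  entries <- unique(entries, by = c("condition", "system", "prefix"))
  structure(list(entries = entries, weights = stats::setNames(w$weight, w$condition),
                 source = path), class = "cci_map")
}

#' @rdname load_cci_map
#' @export
default_cci_map_path <- function() {
  system.file("extdata", "default_cci_map.csv", package = "ishcohort", mustWork = TRUE)
}

#' Charlson Comorbidity Index for one patient
#'
#' Each condition counts at most once however often its codes repeat, and
#' the severe member of each hierarchical pair supersedes the mild one
#' (complicated diabetes over uncomplicated, metastatic solid tumour over
#' any malignancy, moderate/severe over mild liver disease). The band
#' thresholds follow the half-open convention: score < 5 LOW, 5-15 MEDIUM,
#' > 15 HIGH.
#'
#' @param codes character vector of diagnosis codes (any dot style).
#' @param systems coding system per code (`icd9`/`icd10`), recycled.
#' @param map a `cci_map` from [load_cci_map()].
#' @return list with `score`, `conditions_hit` and `band`.
#' @export
#' @examples
#' map <- load_cci_map()
#' cci_score(c("410.00", "250.01"), "icd9", map)
cci_score <- function(codes, systems, map = load_cci_map()) {
  stopifnot(inherits(map, "cci_map"))
  if (length(codes) == 0L) {
    return(list(score = 0L, conditions_hit = character(0), band = cci_band(0L)))
  }
  dt <- data.table::data.table(
    patient_id = 1L, system = rep_len(tolower(systems), length(codes)),
    code = normalize_code(codes)
  )
  res <- cci_score_bulk(dt, map)
  list(score = res$score[1L],
       conditions_hit = strsplit(res$conditions[1L], ";", fixed = TRUE)[[1L]],
       band = res$band[1L])
}

# Vectorized scorer over a diagnosis table with columns patient_id, system,
# code (normalized). Returns one row per distinct patient_id.
cci_score_bulk <- function(diag_table, map) {
  dt <- data.table::as.data.table(diag_table)
  ids <- unique(dt$patient_id)
  if (nrow(dt) == 0L) {
    return(data.table::data.table(patient_id = ids, score = integer(0),
                                  conditions = character(0), band = character(0)))
  }
  uniq <- unique(dt[, .(system, code)])
  maxlen <- max(nchar(uniq$code))
  entries <- map$entries[nchar(prefix) <= maxlen]
  plens <- sort(unique(nchar(entries$prefix)))
  pieces <- lapply(plens, function(L) {
    keep <- nchar(uniq$code) >= L
    data.table::data.table(system = uniq$system[keep], code = uniq$code[keep],
                           prefix = substr(uniq$code[keep], 1L, L))
  })
  hits <- entries[data.table::rbindlist(pieces), on = .(system, prefix), nomatch = NULL,
                  .(condition, weight, system, code = i.code)]
  hits <- unique(hits, by = c("condition", "system", "code"))
  pat <- hits[dt, on = .(system, code), nomatch = NULL,
              .(patient_id = i.patient_id, condition, weight)]
  pat <- unique(pat, by = c("patient_id", "condition"))
  # hierarchy: drop the mild member when the severe member is present
  for (pair in CCI_HIERARCHY) {
    sev <- pat[condition == pair[["severe"]], patient_id]
    if (length(sev)) {
      pat <- pat[!(condition == pair[["mild"]] & patient_id %in% sev)]
    }
  }
  scored <- pat[, .(score = sum(weight),
                    conditions = paste(sort(condition), collapse = ";")),
                by = patient_id]
  out <- data.table::data.table(patient_id = ids)
  out <- scored[out, on = "patient_id"]
  out[is.na(score), `:=`(score = 0L, conditions = "")]
  out[, score := as.integer(score)]
  out[, band := cci_band(score)]
  out[]
}

#' Band a Charlson score
#'
#' @param score integer vector of scores.
#' @return character vector: `LOW` (< 5), `MEDIUM` (5-15), `HIGH` (> 15).
#' @export
cci_band <- function(score) {
  data.table::fcase(score < 5, "LOW", score <= 15, "MEDIUM", default = "HIGH")
}
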