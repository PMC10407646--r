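# ICD code-set loading, normalization and prefix matching.
#
# Code sets are configuration, not constants: each set is a named collection
# of (system, prefix) entries read from a delimited file. A diagnosis code
# matches a set when some entry of the same coding system is a leading
# substring of the dot-stripped, upper-cased code. The bundled default file
# reconstructs the published self-harm algorithm ranges and is fully
# replaceable.

CODESET_NAMES <- c(
  "SELF_HARM_EXPLICIT", "SUICIDAL_IDEATION", "INJURY_POISONING",
  "MENTAL_DISORDER", "TBI", "PTSD"
)
ICD_SYSTEMS <- c("icd9", "icd10")

#' Normalize a raw ICD code
#'
#' Strips surrounding whitespace and embedded dots and upper-cases the
#' result, the canonical form used for all prefix matching. Idempotent.
#'
#' @param raw character vector of codes as recorded.
#' @return character vector of normalized codes.
#' @export
#' @examples
#' normalize_code(c("309.81", "f43.10", "E950.0"))
normalize_code <- function(raw) {
  if (length(raw) == 0L) return(character(0))
  x <- trimws(as.character(raw))
  bad <- is.na(x) | x == ""
  if (any(bad)) {
    stopf("malformed ICD code: empty or missing at position(s) %s",
          paste(utils::head(which(bad), 5L), collapse = ", "))
  }
  toupper(gsub(".", "", x, fixed = TRUE))
}

# Expand a range token "A-B" over normalized prefixes. Supported forms:
#   "800-999"   numeric, zero-padded to the common width
#   "E800-E949" shared leading letters, numeric tail
#   "S00-T88"   single leading letter spanning consecutive letters
# Single prefixes pass through unchanged.
expand_prefix_range <- function(prefix) {
  if (!grepl("-", prefix, fixed = TRUE)) return(prefix)
  parts <- strsplit(prefix, "-", fixed = TRUE)[[1]]
  if (length(parts) != 2L) stopf("cannot parse prefix range '%s'", prefix)
  split1 <- regmatches(parts, regexec("^([A-Z]*)([0-9]+)$", parts))
  if (any(lengths(split1) != 3L)) stopf("cannot parse prefix range '%s'", prefix)
  a_alpha <- split1[[1]][2]; a_num <- split1[[1]][3]
  b_alpha <- split1[[2]][2]; b_num <- split1[[2]][3]
  width <- nchar(a_num)
  if (nchar(b_num) != width) stopf("range '%s' has unequal widths", prefix)
  pad <- function(i) formatC(i, width = width, flag = "0")
  if (identical(a_alpha, b_alpha)) {
    lo <- as.integer(a_num); hi <- as.integer(b_num)
    if (lo > hi) stopf("range '%s' is reversed", prefix)
    return(paste0(a_alpha, pad(lo:hi)))
  }
  if (nchar(a_alpha) != 1L || nchar(b_alpha) != 1L) {
    stopf("range '%s' spans multi-letter prefixes", prefix)
  }
  letters_span <- intToUtf8(utf8ToInt(a_alpha):utf8ToInt(b_alpha), multiple = TRUE)
  if (utf8ToInt(a_alpha) > utf8ToInt(b_alpha)) stopf("range '%s' is reversed", prefix)
  top <- 10^width - 1L
  out <- lapply(seq_along(letters_span), function(i) {
    lo <- if (i == 1L) as.integer(a_num) else 0L
    hi <- if (i == length(letters_span)) as.integer(b_num) else top
    paste0(letters_span[i], pad(lo:hi))
  })
  unlist(out)
}

new_codeset_registry <- function(entries, source = NA_character_) {
  entries <- data.table::as.data.table(entries)[, .(set_name, system, prefix)]
  data.table::setkey(entries, set_name, system, prefix)
  structure(list(entries = entries, source = source), class = "codeset_registry")
}

#' Load an ICD code-set registry from file
#'
#' Reads a delimited file with columns `set_name`, `system` (`icd9`/`icd10`),
#' `prefix` and optional `description`. Prefixes are normalized; range
#' tokens such as `800-999`, `E800-E949` or `S00-T88` are expanded to
#' three-character (or pattern-width) prefixes at load time. All six
#' required sets must be present: SELF_HARM_EXPLICIT, SUICIDAL_IDEATION,
#' INJURY_POISONING, MENTAL_DISORDER, TBI, PTSD.
#'
#' @param path file path; defaults to the bundled reconstruction
#'   [default_codesets_path()].
#' @return a `codeset_registry` object.
#' @export
#' @examples
#' reg <- load_codesets()
#' code_matches(reg, "PTSD", "F4310", "icd10")
load_codesets <- function(path = default_codesets_path()) {
  if (!file.exists(path)) stopf("code-set file not found: %s", path)
  raw <- data.table::fread(path, colClasses = "character")
  need <- c("set_name", "system", "prefix")
  if (!all(need %in% names(raw))) {
    stopf("code-set file %s lacks column(s): %s", path,
          paste(setdiff(need, names(raw)), collapse = ", "))
  }
  raw[, system := tolower(trimws(system))]
  bad_sys <- setdiff(unique(raw$system), ICD_SYSTEMS)
  if (length(bad_sys)) {
    stopf("unknown coding system(s) in %s: %s", path, paste(bad_sys, collapse = ", "))
  }
  raw[, prefix := normalize_code(prefix)]
  entries <- raw[, .(prefix = unlist(lapply(prefix, expand_prefix_range))),
                 by = .(set_name, system)]
  dup <- entries[duplicated(entries, by = c("set_name", "system", "prefix"))]
  if (nrow(dup)) {
    stopf("duplicate code-set entries: %s",
          paste(utils::head(sprintf("%s (%s,%s)", dup$set_name, dup$system, dup$prefix), 5L),
                collapse = "; "))
  }
  missing <- setdiff(CODESET_NAMES, unique(entries$set_name))
  if (length(missing)) {
    stopf("code-set file %s is missing required set(s): %s", path,
          paste(missing, collapse = ", "))
  }
  new_codeset_registry(entries, source = path)
}

#' Path to the bundled default code-set file
#'
#' The defaults reconstruct the self-harm phenotyping ranges used in the
#' administrative-claims literature (explicit self-harm E950-E958 /
#' X71-X83 + T14.91 + intent-encoded poisonings, ideation V62.84 / R45.851,
#' injury or poisoning 800-999 + external-cause injury E-codes / S00-T88,
#' mental disorder 290-319 / F01-F99) together with diagnosis-code
#' definitions of TBI and PTSD. They are a documented reconstruction, not a
#' verbatim published list, and are meant to be replaced where an audited
#' list is available.
#'
#' @return file path of the packaged CSV.
#' @export
default_codesets_path <- function() {
  system.file("extdata", "default_codesets.csv", package = "ishcohort", mustWork = TRUE)
}

#' Write a code-set registry back to file
#'
#' Writes the expanded entries as CSV. `load_codesets(write_codesets(r, f))`
#' reloads to a registry with identical entries.
#'
#' @param registry a `codeset_registry`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_codesets <- function(registry, path) {
  stopifnot(inherits(registry, "codeset_registry"))
  data.table::fwrite(registry$entries, path)
  invisible(path)
}

#' Test codes against one named code set
#'
#' Prefix matching is system-aware: an `icd9` entry never matches an
#' `icd10` code. Unknown systems match nothing (with a warning).
#'
#' @param registry a `codeset_registry`.
#' @param set_name one of the registry's set names.
#' @param codes character vector of codes (normalized internally).
#' @param systems character vector (recycled) of coding systems.
#' @return logical vector, one element per code.
#' @export
code_matches <- function(registry, set_name, codes, systems) {
  stopifnot(inherits(registry, "codeset_registry"))
  if (!set_name %in% registry$entries$set_name) {
    stopf("registry has no set named '%s'", set_name)
  }
  n <- length(codes)
  systems <- rep_len(tolower(systems), n)
  unknown <- !systems %in% ICD_SYSTEMS
  if (any(unknown)) {
    warnf("unknown coding system(s) treated as non-matching: %s",
          paste(unique(systems[unknown]), collapse = ", "))
  }
  flags <- match_codes(
    data.table::data.table(system = systems, code = normalize_code(codes)),
    registry, sets = set_name
  )
  out <- flags[[set_name]]
  out[unknown] <- FALSE
  out
}

# Bulk prefix matcher: for a table with columns `system` and `code`
# (normalized), returns a data.table of logical columns, one per requested
# set. Matching works by exploding each distinct code into its leading
# substrings and joining against the entry table, so cost scales with the
# number of distinct codes, not rows.
match_codes <- function(code_table, registry, sets = CODESET_NAMES) {
  ct <- data.table::as.data.table(code_table)
  uniq <- unique(ct[, .(system, code)])
  if (nrow(uniq) == 0L) {
    return(ct[, stats::setNames(lapply(sets, function(s) logical(0)), sets)])
  }
  maxlen <- max(nchar(uniq$code))
  entries <- registry$entries[set_name %in% sets & nchar(prefix) <= maxlen]
  # explode codes into leading substrings up to the longest entry prefix
  plens <- sort(unique(nchar(entries$prefix)))
  pieces <- lapply(plens, function(L) {
    keep <- nchar(uniq$code) >= L
    data.table::data.table(system = uniq$system[keep], code = uniq$code[keep],
                           prefix = substr(uniq$code[keep], 1L, L))
  })
  exploded <- data.table::rbindlist(pieces)
  hits <- entries[exploded, on = .(system, prefix), nomatch = NULL,
                  .(set_name, system, code = i.code)]
  hits <- unique(hits)
  out <- ct[, .(system, code)]
  for (s in sets) {
    hs <- hits[set_name == s]
    out[, (s) := FALSE]
    if (nrow(hs)) {
      out[hs, on = .(system, code), (s) := TRUE]
    }
  }
  out[, c("system", "code") := NULL]
  out[]
}

#' @export
print.codeset_registry <- function(x, ...) {
  cat("<codeset_registry>", if (!is.na(x$source)) paste0(" from ", x$source), "\n", sep = "")
  tab <- x$entries[, .N, by = .(set_name, system)]
  wide <- data.table::dcast(tab, set_name ~ system, value.var = "N", fill = 0L)
  print(as.data.frame(wide), row.names = FALSE)
  invisible(x)
}
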