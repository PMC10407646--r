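# Shared fixtures: tiny registries, code pools and independent oracles.

# A minimal registry written through the normal file path.
tiny_registry <- function(extra = NULL) {
  rows <- rbind(
    data.frame(set_name = "SELF_HARM_EXPLICIT", system = c("icd9", "icd10"),
               prefix = c("E950-E958", "T14.91")),
    data.frame(set_name = "SELF_HARM_EXPLICIT", system = "icd10", prefix = "X71-X83"),
    data.frame(set_name = "SUICIDAL_IDEATION", system = c("icd9", "icd10"),
               prefix = c("V62.84", "R45.851")),
    data.frame(set_name = "INJURY_POISONING", system = c("icd9", "icd10"),
               prefix = c("800-999", "S00-S99")),
    data.frame(set_name = "INJURY_POISONING", system = "icd10", prefix = "T00-T88"),
    data.frame(set_name = "MENTAL_DISORDER", system = c("icd9", "icd10"),
               prefix = c("290-319", "F01-F99")),
    data.frame(set_name = "TBI", system = c("icd9", "icd10"), prefix = c("850-854", "S06")),
    data.frame(set_name = "PTSD", system = c("icd9", "icd10"), prefix = c("309.81", "F43.1")),
    extra
  )
  f <- tempfile(fileext = ".csv")
  write.csv(rows, f, row.names = FALSE)
  load_codesets(f)
}

# Pool of codes with known set membership, for randomized phenotype bags.
code_pool <- function() {
  rbind(
    data.frame(system = "icd9", code = c("E9500", "E9580", "V6284", "87342",
                                          "9592", "29620", "30981", "85400",
                                          "4011", "V700")),
    data.frame(system = "icd10", code = c("T1491", "X780XXA", "R45851",
                                           "S0990XA", "T391X1A", "F329",
                                           "F4310", "S060X0A", "I10", "Z0000"))
  )
}

# Brute-force three-condition evaluator, deliberately naive: scans every
# prefix of every set with a double loop.
brute_force_conditions <- function(codes, systems, registry) {
  in_set <- function(code, sys, set) {
    e <- registry$entries[registry$entries$set_name == set &
                            registry$entries$system == sys, ]
    any(vapply(e$prefix, function(p) {
      nchar(p) <= nchar(code) && substr(code, 1, nchar(p)) == p
    }, logical(1)))
  }
  codes <- toupper(gsub(".", "", codes, fixed = TRUE))
  sh <- si <- ij <- md <- FALSE
  for (i in seq_along(codes)) {
    sh <- sh || in_set(codes[i], systems[i], "SELF_HARM_EXPLICIT")
    si <- si || in_set(codes[i], systems[i], "SUICIDAL_IDEATION")
    ij <- ij || in_set(codes[i], systems[i], "INJURY_POISONING")
    md <- md || in_set(codes[i], systems[i], "MENTAL_DISORDER")
  }
  out <- c("A_explicit", "B_ideation_plus_injury", "C_injury_plus_mental")[
    c(sh, si && ij, ij && md)]
  out
}

# Expand a 2x2 table into subject-level rows (exposed indicator + outcome).
expand_2x2 <- function(a, b, c, d) {
  data.frame(
    exposed = c(rep(1L, a + b), rep(0L, c + d)),
    outcome = c(rep(1L, a), rep(0L, b), rep(1L, c), rep(0L, d))
  )
}
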