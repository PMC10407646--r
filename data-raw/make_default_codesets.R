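# Builds inst/extdata/default_codesets.csv.
# The lists are a documented reconstruction of the claims-based self-harm
# phenotype ranges (explicit self-harm, ideation, injury/poisoning, mental
# disorder) plus diagnosis-code definitions of TBI and PTSD; range tokens
# are expanded by the loader at run time.

rows <- list(
  # --- explicit suicide attempt / intentional self-harm ------------------
  c("SELF_HARM_EXPLICIT", "icd9",  "E950-E958", "suicide and self-inflicted injury"),
  c("SELF_HARM_EXPLICIT", "icd10", "X71-X83",   "intentional self-harm, external cause"),
  c("SELF_HARM_EXPLICIT", "icd10", "T14.91",    "suicide attempt"),
  # --- suicidal ideation --------------------------------------------------
  c("SUICIDAL_IDEATION",  "icd9",  "V62.84",    "suicidal ideation"),
  c("SUICIDAL_IDEATION",  "icd10", "R45.851",   "suicidal ideations"),
  # --- injury or poisoning ------------------------------------------------
  c("INJURY_POISONING",   "icd9",  "800-999",   "injury and poisoning"),
  c("INJURY_POISONING",   "icd9",  "E800-E949", "external causes of accidental injury"),
  c("INJURY_POISONING",   "icd10", "S00-S99",   "injuries"),
  c("INJURY_POISONING",   "icd10", "T00-T88",   "injury, poisoning, other external causes"),
  # --- mental disorder ----------------------------------------------------
  c("MENTAL_DISORDER",    "icd9",  "290-319",   "mental disorders"),
  c("MENTAL_DISORDER",    "icd10", "F01-F99",   "mental and behavioural disorders"),
  # --- traumatic brain injury --------------------------------------------
  c("TBI", "icd9",  "800",     "fracture of vault of skull"),
  c("TBI", "icd9",  "801",     "fracture of base of skull"),
  c("TBI", "icd9",  "803",     "other skull fracture"),
  c("TBI", "icd9",  "804",     "multiple fractures involving skull"),
  c("TBI", "icd9",  "850-854", "intracranial injury"),
  c("TBI", "icd9",  "950.1",   "injury to optic chiasm"),
  c("TBI", "icd9",  "950.2",   "injury to optic pathways"),
  c("TBI", "icd9",  "950.3",   "injury to visual cortex"),
  c("TBI", "icd9",  "959.01",  "head injury, unspecified"),
  c("TBI", "icd9",  "V15.52",  "personal history of TBI"),
  c("TBI", "icd10", "S02",     "fracture of skull and facial bones"),
  c("TBI", "icd10", "S04.02",  "injury of optic chiasm"),
  c("TBI", "icd10", "S04.03",  "injury of optic tract and pathways"),
  c("TBI", "icd10", "S04.04",  "injury of visual cortex"),
  c("TBI", "icd10", "S06",     "intracranial injury"),
  c("TBI", "icd10", "S07",     "crushing injury of head"),
  c("TBI", "icd10", "T74.4",   "shaken infant syndrome"),
  # --- posttraumatic stress disorder -------------------------------------
  c("PTSD", "icd9",  "309.81", "posttraumatic stress disorder"),
  c("PTSD", "icd10", "F43.1",  "post-traumatic stress disorder")
)

# Intent-encoded poisoning self-harm: ICD-10-CM encodes intentional
# self-harm in the sixth character ('2') of the T36-T65 poisoning codes;
# enumerate the X-filler subcategory pattern Tnn.mX2 per category.
for (cat3 in 36:65) {
  for (sub in 0:9) {
    rows[[length(rows) + 1L]] <- c(
      "SELF_HARM_EXPLICIT", "icd10", sprintf("T%d.%dX2", cat3, sub),
      sprintf("poisoning T%d.%d, intentional self-harm", cat3, sub)
    )
  }
}

df <- do.call(rbind.data.frame, rows)
names(df) <- c("set_name", "system", "prefix", "description")
write.csv(df, file.path("inst", "extdata", "default_codesets.csv"), row.names = FALSE)
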