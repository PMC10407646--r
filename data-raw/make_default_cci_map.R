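# Builds inst/extdata/default_cci_map.csv: a Quan-style administrative-data
# mapping of ICD-9-CM / ICD-10 prefixes to the 17 Charlson conditions, with
# the original condition weights (1/2/3/6). Range tokens are expanded by the
# loader.

m <- function(condition, weight, system, prefixes) {
  data.frame(condition = condition, weight = weight, system = system,
             prefix = prefixes, stringsAsFactors = FALSE)
}

map <- rbind(
  m("myocardial_infarction", 1, "icd9",  c("410", "412")),
  m("myocardial_infarction", 1, "icd10", c("I21", "I22", "I25.2")),

  m("congestive_heart_failure", 1, "icd9",
    c("398.91", "402.01", "402.11", "402.91", "404.01", "404.03", "404.11",
      "404.13", "404.91", "404.93", "425.4-425.9", "428")),
  m("congestive_heart_failure", 1, "icd10",
    c("I09.9", "I11.0", "I13.0", "I13.2", "I25.5", "I42.0", "I42.5-I42.9",
      "I43", "I50", "P29.0")),

  m("peripheral_vascular_disease", 1, "icd9",
    c("093.0", "437.3", "440", "441", "443.1-443.9", "447.1", "557.1",
      "557.9", "V43.4")),
  m("peripheral_vascular_disease", 1, "icd10",
    c("I70", "I71", "I73.1", "I73.8", "I73.9", "I77.1", "I79.0", "I79.2",
      "K55.1", "K55.8", "K55.9", "Z95.8", "Z95.9")),

  m("cerebrovascular_disease", 1, "icd9", c("362.34", "430-438")),
  m("cerebrovascular_disease", 1, "icd10", c("G45", "G46", "H34.0", "I60-I69")),

  m("dementia", 1, "icd9", c("290", "294.1", "331.2")),
  m("dementia", 1, "icd10", c("F00-F03", "F05.1", "G30", "G31.1")),

  m("chronic_pulmonary_disease", 1, "icd9",
    c("416.8", "416.9", "490-505", "506.4", "508.1", "508.8")),
  m("chronic_pulmonary_disease", 1, "icd10",
    c("I27.8", "I27.9", "J40-J47", "J60-J67", "J68.4", "J70.1", "J70.3")),

  m("rheumatic_disease", 1, "icd9",
    c("446.5", "710.0-710.4", "714.0-714.2", "714.8", "725")),
  m("rheumatic_disease", 1, "icd10",
    c("M05", "M06", "M31.5", "M32-M34", "M35.1", "M35.3", "M36.0")),

  m("peptic_ulcer_disease", 1, "icd9", "531-534"),
  m("peptic_ulcer_disease", 1, "icd10", "K25-K28"),

  m("mild_liver_disease", 1, "icd9",
    c("070.22", "070.23", "070.32", "070.33", "070.44", "070.54", "070.6",
      "070.9", "570", "571", "573.3", "573.4", "573.8", "573.9", "V42.7")),
  m("mild_liver_disease", 1, "icd10",
    c("B18", "K70.0-K70.3", "K70.9", "K71.3-K71.5", "K71.7", "K73", "K74",
      "K76.0", "K76.2-K76.4", "K76.8", "K76.9", "Z94.4")),

  m("diabetes_uncomplicated", 1, "icd9", c("250.0-250.3", "250.8", "250.9")),
  m("diabetes_uncomplicated", 1, "icd10",
    c("E10.0", "E10.1", "E10.6", "E10.8", "E10.9",
      "E11.0", "E11.1", "E11.6", "E11.8", "E11.9",
      "E12.0", "E12.1", "E12.6", "E12.8", "E12.9",
      "E13.0", "E13.1", "E13.6", "E13.8", "E13.9",
      "E14.0", "E14.1", "E14.6", "E14.8", "E14.9")),

  m("diabetes_complicated", 2, "icd9", "250.4-250.7"),
  m("diabetes_complicated", 2, "icd10",
    c("E10.2-E10.5", "E10.7", "E11.2-E11.5", "E11.7", "E12.2-E12.5",
      "E12.7", "E13.2-E13.5", "E13.7", "E14.2-E14.5", "E14.7")),

  m("hemiplegia_paraplegia", 2, "icd9",
    c("334.1", "342", "343", "344.0-344.6", "344.9")),
  m("hemiplegia_paraplegia", 2, "icd10",
    c("G04.1", "G11.4", "G80.1", "G80.2", "G81", "G82", "G83.0-G83.4", "G83.9")),

  m("renal_disease", 2, "icd9",
    c("403.01", "403.11", "403.91", "404.02", "404.12", "404.92", "582",
      "583.0-583.7", "585", "586", "588.0", "V42.0", "V45.1", "V56")),
  m("renal_disease", 2, "icd10",
    c("I12.0", "I13.1", "N03.2-N03.7", "N05.2-N05.7", "N18", "N19",
      "N25.0", "Z49.0-Z49.2", "Z94.0", "Z99.2")),

  m("any_malignancy", 2, "icd9", c("140-172", "174-195", "200-208", "238.6")),
  m("any_malignancy", 2, "icd10",
    c("C00-C26", "C30-C34", "C37-C41", "C43", "C45-C58", "C60-C76",
      "C81-C85", "C88", "C90-C97")),

  m("moderate_severe_liver_disease", 3, "icd9",
    c("456.0-456.2", "572.2-572.8")),
  m("moderate_severe_liver_disease", 3, "icd10",
    c("I85.0", "I85.9", "I86.4", "I98.2", "K70.4", "K71.1", "K72.1",
      "K72.9", "K76.5", "K76.6", "K76.7")),

  m("metastatic_solid_tumor", 6, "icd9", "196-199"),
  m("metastatic_solid_tumor", 6, "icd10", "C77-C80"),

  m("aids_hiv", 6, "icd9", "042-044"),
  m("aids_hiv", 6, "icd10", c("B20-B22", "B24"))
)

write.csv(map, file.path("inst", "extdata", "default_cci_map.csv"), row.names = FALSE)
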