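Package: ishcohort
Title: Retrospective EHR Cohorts of Intentional Self-Harm After TBI and PTSD
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and analysing retrospective cohorts of
    intentional self-harm from encounter-level administrative health records.
    Implements ICD-9-CM/ICD-10 code-set matching, a three-condition encounter
    phenotype for suicide attempt and other intentional self-harm, index-date
    assignment with distribution-matched sampling for non-cases, five-year
    lookback exposure classification (traumatic brain injury and posttraumatic
    stress disorder), utilization stratification, Charlson comorbidity scoring,
    and stratified prevalence, odds-ratio and multivariable logistic-regression
    estimation. Includes a synthetic electronic-health-record generator with
    exact fixture and stochastic logit modes for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
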