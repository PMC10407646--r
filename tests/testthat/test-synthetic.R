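test_that("generator configs validate mode requirements and feasibility", {
  expect_error(generator_config(mode = "fixture"), "cell_counts")
  expect_error(generator_config(mode = "stochastic", n = 10), "logit_params")
  expect_error(generator_config(mode = "stochastic", logit_params = list(intercept = 0)), "requires n")
  cc <- data.frame(stratum = "LOW", group = "NEITHER", self_harm = 0, n = 5)
  expect_error(generator_config(mode = "fixture", cell_counts = cc,
                                visit_bands = list(LOW = c(4, 2000),
                                                   MEDIUM = c(36, 76), HIGH = c(81, 140))),
               "exceeds")
  expect_error(generator_config(mode = "fixture", cell_counts = cc,
                                visit_bands = list(LOW = c(200, 210),
                                                   MEDIUM = c(36, 76), HIGH = c(81, 140))),
               "no stationary grid step")
  bad <- data.frame(stratum = "LOW", group = "NEITHER", self_harm = 0, n = -1)
  expect_error(generator_config(mode = "fixture", cell_counts = bad), "non-negative")
})

test_that("generation is deterministic given the seed", {
  cfg <- generator_config(mode = "fixture", cell_counts = table2_cell_counts(1 / 5000),
                          seed = 31L)
  d1 <- generate_cohort_data(cfg)
  d2 <- generate_cohort_data(cfg)
  expect_identical(d1$patients, d2$patients)
  expect_identical(d1$encounters, d2$encounters)
  expect_identical(d1$diagnoses, d2$diagnoses)
  expect_identical(d1$truth, d2$truth)
  d3 <- generate_cohort_data(generator_config(mode = "fixture",
                                              cell_counts = table2_cell_counts(1 / 5000),
                                              seed = 32L))
  expect_false(identical(d1$encounters, d3$encounters))
})

test_that("a single comorbid-case cell yields patients with TBI, PTSD and a flagged index", {
  cc <- data.frame(stratum = "HIGH", group = "COMORBID", self_harm = 1, n = 3)
  dat <- generate_cohort_data(generator_config(mode = "fixture", cell_counts = cc, seed = 5))
  expect_equal(nrow(dat$truth), 3L)
  reg <- load_codesets()
  enc <- dat$encounters
  diag <- dat$diagnoses
  flagged <- classify_encounters(enc, diag, reg)
  first <- first_self_harm(flagged)
  expect_setequal(first$patient_id, dat$truth$patient_id)
  expect_equal(first[order(first$patient_id), ]$index_date,
               dat$truth[order(dat$truth$patient_id), ]$index_date)
  dated <- merge(diag, enc, by = "encounter_id")
  for (pid in dat$truth$patient_id) {
    idx <- dat$truth$index_date[dat$truth$patient_id == pid]
    got <- exposure_in_window(dated[dated$patient_id == pid, ],
                              c(add_years(idx, -5), idx), reg)
    expect_equal(got$group, "COMORBID")
  }
})

test_that("case exposure codes never leak outside the lookback window", {
  cfg <- generator_config(mode = "fixture", cell_counts = table2_cell_counts(1 / 3000),
                          seed = 12L)
  dat <- generate_cohort_data(cfg)
  reg <- load_codesets()
  dated <- merge(dat$diagnoses, dat$encounters, by = "encounter_id")
  expo <- dated[code_matches(reg, "TBI", dated$icd_code, dated$system) |
                  code_matches(reg, "PTSD", dated$icd_code, dated$system), ]
  cases <- dat$truth[dat$truth$outcome == 1L, ]
  ce <- merge(expo, cases[, c("patient_id", "index_date")], by = "patient_id")
  expect_true(all(ce$date >= add_years(ce$index_date, -5)))
  expect_true(all(ce$date < ce$index_date))
})

test_that("non-case classification is invariant over every admissible index date", {
  cc <- data.frame(stratum = rep(c("LOW", "MEDIUM", "HIGH"), each = 2),
                   group = rep(c("COMORBID", "TBI_ONLY"), 3),
                   self_harm = 0, n = 4)
  cfg <- generator_config(mode = "fixture", cell_counts = cc, seed = 77, cci_plant_prob = 0)
  dat <- generate_cohort_data(cfg)
  reg <- load_codesets()
  dated <- merge(dat$diagnoses, dat$encounters, by = "encounter_id")
  set.seed(99)
  for (pid in dat$truth$patient_id) {
    enc_p <- dat$encounters[dat$encounters$patient_id == pid, ]
    in_win <- enc_p$date[enc_p$date >= cfg$window_start & enc_p$date <= cfg$window_end]
    probes <- sample(in_win, min(5L, length(in_win)))
    truth_row <- dat$truth[dat$truth$patient_id == pid, ]
    for (d in as.list(probes)) {
      lb <- add_years(d, -5)
      got <- exposure_in_window(dated[dated$patient_id == pid, ], c(lb, d), reg)
      expect_equal(got$group, truth_row$group)
      nvis <- length(unique(enc_p$date[enc_p$date >= lb & enc_p$date < d]))
      expect_equal(utilization_stratum(nvis / 5), truth_row$stratum)
    }
  }
})

test_that("yearly visit counts land in the configured utilization band", {
  cc <- data.frame(stratum = c("LOW", "MEDIUM", "HIGH"), group = "NEITHER",
                   self_harm = c(1, 1, 1), n = 30)
  dat <- generate_cohort_data(generator_config(mode = "fixture", cell_counts = cc, seed = 2))
  counts <- ishcohort:::lookback_visit_counts(
    dat$encounters, data.frame(patient_id = dat$truth$patient_id,
                               index_date = dat$truth$index_date))
  merged <- merge(counts, dat$truth[, c("patient_id", "stratum")], by = "patient_id")
  yearly <- merged$visits / 5
  expect_true(all(yearly[merged$stratum == "LOW"] <= 6.6))
  expect_true(all(yearly[merged$stratum == "MEDIUM"] > 6.6 &
                    yearly[merged$stratum == "MEDIUM"] <= 15.6))
  expect_true(all(yearly[merged$stratum == "HIGH"] > 15.6))
  expect_true(all(merged$visits >= 2))
})

test_that("stochastic outcomes follow the logit model", {
  design <- data.frame(group = rep(c("NEITHER", "COMORBID"), each = 5000))
  set.seed(10)
  sym <- simulate_outcomes(design, list(intercept = 0))
  expect_true(abs(mean(sym$outcome) - 0.5) < 0.02)
  none <- simulate_outcomes(design, list(intercept = -30))
  expect_equal(sum(none$outcome), 0L)
  eff <- simulate_outcomes(design, list(intercept = -3, group = c(COMORBID = 2)))
  expect_equal(unique(round(eff$p[design$group == "COMORBID"], 10)),
               round(plogis(-1), 10))
  expect_error(simulate_outcomes(design, list(intercept = Inf)), "non-finite")
})

test_that("stochastic tables plant a bivariable log-odds recoverable downstream", {
  cfg <- generator_config(
    mode = "stochastic", n = 30000,
    logit_params = list(intercept = qlogis(0.02), group = c(COMORBID = log(6.72))),
    group_probs = c(NEITHER = 0.9, COMORBID = 0.1),
    seed = 8
  )
  dat <- generate_cohort_data(cfg)
  tr <- dat$truth
  a <- sum(tr$outcome[tr$group == "COMORBID"]); b <- sum(tr$group == "COMORBID") - a
  c <- sum(tr$outcome[tr$group == "NEITHER"]); d <- sum(tr$group == "NEITHER") - c
  o <- odds_ratio(a, b, c, d)
  expect_true(o$ci_low < 6.72 && 6.72 < o$ci_high)
})
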