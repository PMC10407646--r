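test_that("index assignment: cases keep first events; forced controls land in the case month", {
  cases <- data.frame(patient_id = 1:3, index_date = as.Date("2010-06-15") + 0:2)
  ctrl <- data.frame(patient_id = rep(10L, 4), date = as.Date("2010-06-05") + c(0, 3, 9, 20))
  asg <- assign_index_dates(cases, ctrl, seed = 1)
  expect_equal(asg[asg$is_case, ]$index_date, cases$index_date)
  got <- asg[!asg$is_case, ]
  expect_equal(format(got$index_date, "%Y-%m"), "2010-06")
  expect_true(got$index_date %in% ctrl$date)
  expect_equal(got$source, "matched_random")
})

test_that("index assignment is reproducible and bin shares follow the case distribution", {
  # two case bins at 50/50; controls with encounters in both bins
  cases <- data.frame(patient_id = 1:200,
                      index_date = rep(as.Date(c("2010-03-10", "2014-09-10")), 100))
  n_ctrl <- 4000
  ctrl <- data.frame(
    patient_id = rep(1000L + seq_len(n_ctrl), each = 2),
    date = rep(as.Date(c("2010-03-05", "2014-09-20")), n_ctrl)
  )
  asg1 <- assign_index_dates(cases, ctrl, seed = 42)
  asg2 <- assign_index_dates(cases, ctrl, seed = 42)
  expect_identical(asg1, asg2)
  share <- mean(format(asg1[!asg1$is_case, ]$index_date, "%Y") == "2010")
  # binomial 99% band around 0.5 at n = 4000
  expect_true(abs(share - 0.5) < 2.58 * sqrt(0.25 / n_ctrl))
})

test_that("a control without encounters in the sampled bin falls back to the nearest bin", {
  cases <- data.frame(patient_id = 1L, index_date = as.Date("2012-05-15"))
  # control has no May-2012 encounter; nearest encounter bin is 3 months later
  ctrl <- data.frame(patient_id = 2L, date = as.Date("2012-08-20"))
  asg <- assign_index_dates(cases, ctrl, seed = 7)
  expect_equal(asg[!asg$is_case, ]$index_date, as.Date("2012-08-20"))
  # tie: encounters 2 months before and 2 months after -> earlier bin wins
  ctrl2 <- data.frame(patient_id = 2L, date = as.Date(c("2012-03-20", "2012-07-20")))
  asg2 <- assign_index_dates(cases, ctrl2, seed = 7)
  expect_equal(asg2[!asg2$is_case, ]$index_date, as.Date("2012-03-20"))
})

test_that("with no cases, controls sample uniformly over their own encounters", {
  ctrl <- data.frame(patient_id = rep(1:50, each = 3),
                     date = rep(as.Date("2010-01-01") + c(0, 400, 800), 50))
  expect_message(asg <- assign_index_dates(
    data.frame(patient_id = integer(0), index_date = as.Date(character(0))),
    ctrl, seed = 3), "uniformly")
  expect_equal(nrow(asg), 50L)
  expect_true(all(asg$index_date %in% ctrl$date))
})

test_that("eligibility keeps two half-open-lookback visits and drops the rest", {
  asg <- data.frame(patient_id = 1:3, index_date = as.Date("2015-01-01"),
                    is_case = FALSE, source = "matched_random", sampling_bin = NA)
  enc <- rbind(
    data.frame(patient_id = 1L, date = as.Date(c("2012-01-01", "2013-01-01"))),   # 2 in lookback
    data.frame(patient_id = 2L, date = as.Date(c("2012-01-01", "2015-02-01",      # 1 in lookback
                                                 "2015-03-01", "2015-04-01"))),
    data.frame(patient_id = 3L, date = as.Date(c("2010-01-01", "2015-01-01",      # boundary dates
                                                 "2012-06-01")))
  )
  kept <- apply_eligibility(enc, asg)
  # patient 3: visit exactly at index-5y counts, visit at index does not -> 2 qualifying
  expect_setequal(kept$patient_id, c(1L, 3L))
  expect_equal(attr(kept, "exclusions")$n, 1L)
})

test_that("utilization arithmetic and strata match the printed cut points", {
  mk <- function(n_dates) {
    list(enc = data.frame(patient_id = 1L,
                          date = as.Date("2015-01-01") - seq_len(n_dates)),
         asg = data.frame(patient_id = 1L, index_date = as.Date("2015-01-01")))
  }
  for (case in list(list(33L, 6.6, "LOW"), list(78L, 15.6, "MEDIUM"), list(79L, 15.8, "HIGH"))) {
    f <- mk(case[[1]])
    u <- compute_utilization(f$enc, f$asg)
    expect_equal(u$yearly_visits, case[[2]])
    expect_equal(u$stratum, case[[3]])
  }
})

test_that("empirical thresholds split the cohort near 50/25/25", {
  set.seed(21)
  n <- 2000
  visits <- sample(2:150, n, replace = TRUE)
  asg <- data.frame(patient_id = seq_len(n), index_date = as.Date("2016-01-01"))
  enc <- data.frame(patient_id = rep(seq_len(n), visits),
                    date = as.Date("2016-01-01") - sequence(visits))
  u <- compute_utilization(enc, asg, thresholds = "empirical")
  shares <- as.numeric(table(factor(u$stratum, c("LOW", "MEDIUM", "HIGH")))) / n
  expect_true(abs(shares[1] - 0.50) < 0.03)
  expect_true(abs(shares[2] - 0.25) < 0.03)
  expect_true(abs(shares[3] - 0.25) < 0.03)
})

test_that("covariates bin at the index date with declared catch-alls", {
  reg <- tiny_registry()
  map <- load_cci_map()
  patients <- data.frame(
    patient_id = 1:3,
    birth_date = as.Date(c("1980-01-02", "1939-01-01", "1970-01-01")),
    sex = c("M", "F", "M"),
    race = c("White", "Martian", "Black"),
    ethnicity = c("Hispanic", "NotHispanic", "NotHispanic"),
    marital = c("Married", NA, "CivilUnion"),
    service_connection = c(50, NA, 40)
  )
  asg <- data.frame(patient_id = 1:3, index_date = as.Date("2010-01-01"),
                    is_case = c(TRUE, FALSE, FALSE),
                    source = c("first_event", "matched_random", "matched_random"),
                    sampling_bin = NA)
  enc <- data.frame(encounter_id = 1:6, patient_id = rep(1:3, each = 2),
                    date = rep(as.Date(c("2007-05-01", "2008-05-01")), 3))
  diag <- data.frame(encounter_id = 1L, icd_code = "309.81", system = "icd9")
  u <- compute_utilization(enc, asg)
  cohort <- build_cohort_table(patients, enc, diag, asg, u, reg, map)
  row1 <- cohort[cohort$patient_id == 1L, ]
  expect_equal(row1$age_band, "<30")       # age 29 at index, boundary
  expect_equal(row1$sc_band, ">=50")       # exactly 50 percent
  expect_equal(row1$group, "PTSD_ONLY")
  expect_equal(cohort[cohort$patient_id == 2L, ]$age_band, ">=70")
  expect_equal(cohort[cohort$patient_id == 2L, ]$marital, "Unknown")
  expect_equal(cohort[cohort$patient_id == 2L, ]$race, "Other")
  expect_equal(cohort[cohort$patient_id == 2L, ]$sc_band, "None")
  expect_equal(cohort[cohort$patient_id == 3L, ]$marital, "Unknown")
  expect_equal(cohort[cohort$patient_id == 3L, ]$sc_band, "<50")
  expect_equal(attr(cohort, "recoded")$n, c(1L, 2L))
})
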