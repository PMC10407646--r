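test_that("prevalence reproduces printed percentages and guards the denominator", {
  expect_equal(as.numeric(prevalence(6778, 51517)), 11.63)
  expect_equal(as.numeric(prevalence(21979, 1123012)), 1.92)
  expect_equal(as.numeric(prevalence(0, 10)), 0)
  expect_equal(attr(prevalence(1, 2), "unrounded"), 100 / 3)
  expect_error(prevalence(0, 0), "denominator")
})

test_that("half-up rounding rounds .005 upward", {
  expect_equal(round_half_up(0.125, 2), 0.13)
  expect_equal(round_half_up(2.675, 2), 2.68)  # would be 2.67 under half-even
  expect_equal(round_half_up(-0.125, 2), -0.13)
})

test_that("odds ratios match the cross-product with Woolf intervals", {
  o <- odds_ratio(6778, 51517, 21979, 1123012)
  expect_equal(round_half_up(o$or, 2), 6.72)
  expect_equal(round_half_up(o$ci_low, 2), 6.53)
  expect_equal(round_half_up(o$ci_high, 2), 6.92)
  expect_equal(round_half_up(odds_ratio(2335, 42498, 21979, 1123012)$or, 2), 2.81)
  expect_equal(odds_ratio(5, 5, 5, 5)$or, 1)
  # swapping exposure labels inverts the estimate exactly
  for (cells in list(c(3, 7, 11, 13), c(40, 2, 9, 77), c(100, 50, 25, 200))) {
    o1 <- odds_ratio(cells[1], cells[2], cells[3], cells[4])
    o2 <- odds_ratio(cells[3], cells[4], cells[1], cells[2])
    expect_equal(o1$or * o2$or, 1, tolerance = 1e-12)
  }
  # zero cell: continuity-corrected and flagged
  oz <- odds_ratio(0, 10, 5, 5)
  expect_equal(oz$method, "woolf_continuity")
  expect_equal(oz$or, (0.5 * 5.5) / (10.5 * 5.5))
  expect_error(odds_ratio(0, 0, 0, 0), "empty")
})

test_that("the IRLS fit matches glm and the closed-form saturated identity", {
  set.seed(314)
  dat <- expand_2x2(30, 170, 55, 745)
  fit <- fit_logistic(dat, "outcome", "exposed")
  g <- glm(outcome ~ exposed, data = dat, family = binomial,
           control = glm.control(epsilon = 1e-12))
  expect_equal(fit$coefficients$estimate, unname(coef(g)), tolerance = 1e-9)
  expect_equal(fit$coefficients$se, unname(sqrt(diag(vcov(g)))), tolerance = 1e-9)
  o <- odds_ratio(30, 170, 55, 745)
  co <- fit$coefficients[fit$coefficients$term == "exposed", ]
  expect_equal(co$estimate, o$log_or, tolerance = 1e-8)
  expect_equal(co$se, o$se, tolerance = 1e-8)
  expect_true(fit$converged)
  expect_lt(fit$max_score, 1e-8)
})

test_that("null data keep coefficients within three standard errors", {
  set.seed(88)
  ok <- 0L
  for (s in 1:20) {
    n <- 3000
    dat <- data.frame(outcome = rbinom(n, 1, 0.3),
                      g = sample(c("a", "b", "c", "d"), n, TRUE))
    fit <- fit_logistic(dat, "outcome", "g")
    co <- fit$coefficients[fit$coefficients$term != "(Intercept)", ]
    if (all(abs(co$estimate) < 3 * co$se)) ok <- ok + 1L
  }
  expect_gte(ok, 18L)
})

test_that("degenerate designs are flagged or rejected", {
  dat <- data.frame(outcome = c(1, 1, 1, 0, 0, 0), x = c(1, 1, 1, 0, 0, 0))
  expect_warning(fit <- fit_logistic(dat, "outcome", "x"), "separation")
  expect_true(fit$separation)
  dat2 <- data.frame(outcome = rbinom(50, 1, 0.5), x = rnorm(50))
  dat2$y <- dat2$x
  expect_error(fit_logistic(dat2, "outcome", c("x", "y")), "rank deficient")
  expect_error(fit_logistic(data.frame(outcome = rep(1, 5), x = rnorm(5)),
                            "outcome", "x"), "non-case")
  expect_message(
    fit3 <- fit_logistic(data.frame(outcome = rbinom(100, 1, 0.4),
                                    z = "only", x = rnorm(100)),
                         "outcome", c("z", "x")),
    "single observed level")
  expect_false("zonly" %in% fit3$coefficients$term)
})

test_that("forced and largest-category reference levels are honoured and logged", {
  set.seed(9)
  dat <- data.frame(outcome = rbinom(300, 1, 0.4),
                    group = sample(c("NEITHER", "COMORBID"), 300, TRUE, c(0.3, 0.7)))
  fit <- fit_logistic(dat, "outcome", "group", ref_levels = list(group = "NEITHER"))
  expect_equal(fit$reference_levels$group, "NEITHER")
  expect_true("groupCOMORBID" %in% fit$coefficients$term)
  fit2 <- fit_logistic(dat, "outcome", "group")
  expect_equal(fit2$reference_levels$group, "COMORBID")  # largest category
})

test_that("stratified analysis composes the per-cell estimators and ignores row order", {
  set.seed(42)
  n <- 4000
  cohort <- data.frame(
    patient_id = seq_len(n),
    stratum = sample(c("LOW", "HIGH"), n, TRUE),
    group = sample(c("NEITHER", "TBI_ONLY", "PTSD_ONLY", "COMORBID"), n, TRUE,
                   c(0.6, 0.1, 0.2, 0.1)),
    outcome = rbinom(n, 1, 0.15),
    age_band = sample(c("<30", "45-69"), n, TRUE),
    sex = sample(c("M", "F"), n, TRUE, c(0.9, 0.1)),
    race = sample(c("White", "Black"), n, TRUE),
    ethnicity = "NotHispanic", marital = "Married", sc_band = "None",
    cci_band = "LOW"
  )
  res <- suppressWarnings(stratified_analysis(cohort))
  cells <- res$cells
  for (s in c("LOW", "HIGH")) {
    wide <- data.table::dcast(cells[cells$stratum == s, ],
                              group ~ self_harm, value.var = "n")
    ref <- wide[wide$group == "NEITHER", ]
    for (g in c("TBI_ONLY", "PTSD_ONLY", "COMORBID")) {
      gi <- wide[wide$group == g, ]
      expect_equal(res[[s]]$odds_ratios[[g]]$or,
                   odds_ratio(gi$`1`, gi$`0`, ref$`1`, ref$`0`)$or)
    }
    # bivariable OR equals the saturated logistic fit per group
    expect_true(all(c("minimal", "full") %in% names(res[[s]]$fits)))
  }
  perm <- cohort[sample.int(n), ]
  res2 <- suppressWarnings(stratified_analysis(perm))
  expect_equal(res2$HIGH$odds_ratios$COMORBID$or, res$HIGH$odds_ratios$COMORBID$or)
  expect_equal(res2$LOW$fits$full$coefficients$estimate,
               res$LOW$fits$full$coefficients$estimate)
  # totals identity: group cases sum to stratum cases
  tot <- sum(cells[cells$self_harm == 1 & cells$stratum == "HIGH", ]$n)
  expect_equal(tot, sum(cohort$outcome[cohort$stratum == "HIGH"]))
  # empty stratum warned and skipped
  expect_warning(stratified_analysis(cohort, models = "bivariable"), "MEDIUM")
})
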