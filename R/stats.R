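# Prevalence, 2x2 odds ratios with Woolf intervals, and multivariable
# logistic regression by iteratively reweighted least squares.

#' Prevalence as a percentage
#'
#' @param cases,noncases non-negative counts.
#' @param digits report-layer decimal places, rounded half-up; `NULL`
#'   returns the unrounded value. The unrounded value is always kept in the
#'   `"unrounded"` attribute.
#' @return percentage of cases among cases + noncases.
#' @export
#' @examples
#' prevalence(6778, 51517)
prevalence <- function(cases, noncases, digits = 2L) {
  total <- cases + noncases
  if (any(total <= 0)) stopf("prevalence undefined: zero denominator")
  pct <- 100 * cases / total
  out <- if (is.null(digits)) pct else round_half_up(pct, digits)
  attr(out, "unrounded") <- pct
  out
}

#' Odds ratio for a 2x2 table with a Woolf confidence interval
#'
#' `a` exposed cases, `b` exposed non-cases, `c` unexposed cases, `d`
#' unexposed non-cases. The point estimate is the cross-product ratio
#' (a d)/(b c); the 95% interval is log-normal (Woolf):
#' exp(ln OR +/- 1.96 sqrt(1/a + 1/b + 1/c + 1/d)). When any cell is zero
#' the Haldane-Anscombe continuity correction (+0.5 to every cell) is
#' applied and the method is flagged.
#'
#' @param a,b,c,d non-negative integer cells.
#' @return an `or_estimate`: list with `or`, `ci_low`, `ci_high`, `log_or`,
#'   `se`, `method`.
#' @export
#' @examples
#' odds_ratio(6778, 51517, 21979, 1123012)
odds_ratio <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(cells < 0)) stopf("contingency cells must be non-negative")
  if (sum(cells) == 0) stopf("contingency table is empty")
  method <- "woolf"
  if (any(cells == 0)) {
    cells <- cells + 0.5
    method <- "woolf_continuity"
  }
  lor <- log(cells[["a"]]) + log(cells[["d"]]) - log(cells[["b"]]) - log(cells[["c"]])
  se <- sqrt(sum(1 / cells))
  structure(
    list(or = exp(lor), ci_low = exp(lor - 1.96 * se),
         ci_high = exp(lor + 1.96 * se), log_or = lor, se = se, method = method),
    class = "or_estimate"
  )
}

#' @export
print.or_estimate <- function(x, ...) {
  cat(sprintf("OR %.2f (95%% CI %.2f-%.2f) [%s]\n",
              x$or, x$ci_low, x$ci_high, x$method))
  invisible(x)
}

# Covariate sets of the two adjusted models.
MODEL_COVARIATES <- list(
  bivariable = character(0),
  minimal = c("age_band", "sex", "race"),
  full = c("age_band", "sex", "race", "ethnicity", "marital", "sc_band", "cci_band")
)

#' Logistic regression by iteratively reweighted least squares
#'
#' Maximum-likelihood logistic fit with Newton/IRLS updates. Convergence is
#' declared when the maximum absolute score (gradient of the
#' log-likelihood) falls below `tol` (default 1e-8), capped at `max_iter`
#' iterations; a fit that stops at the cap is flagged, not silently
#' returned. Wald 95% intervals are exp(coef +/- 1.96 SE). Factors are
#' dummy-coded with the largest observed category as reference (recorded in
#' the result); factors with a single observed level are dropped with a
#' message. Quasi-separation is flagged when any coefficient passes 15 in
#' absolute value. A rank-deficient design is an error naming the aliased
#' columns.
#'
#' @param data data.frame of one row per subject.
#' @param outcome name of the 0/1 outcome column.
#' @param terms character vector of predictor column names.
#' @param ref_levels optional named list forcing the reference level of
#'   specific factor terms (e.g. `list(group = "NEITHER")`); other factors
#'   keep the largest-category reference.
#' @param tol score convergence tolerance.
#' @param max_iter iteration cap.
#' @return an `ish_fit`: coefficients, standard errors, odds ratios with
#'   CIs, convergence metadata, reference levels.
#' @export
fit_logistic <- function(data, outcome = "outcome", terms, ref_levels = list(),
                         tol = 1e-8, max_iter = 50L) {
  dt <- data.table::as.data.table(data)
  y <- as.numeric(dt[[outcome]])
  if (any(!y %in% c(0, 1))) stopf("outcome must be 0/1")
  if (all(y == 0) || all(y == 1)) stopf("need at least one case and one non-case")

  kept <- character(0)
  refs <- list()
  for (tm in terms) {
    v <- dt[[tm]]
    if (is.null(v)) stopf("term '%s' not found in data", tm)
    if (is.character(v) || is.factor(v)) {
      v <- as.character(v)
      lev <- names(sort(table(v), decreasing = TRUE))
      if (length(lev) < 2L) {
        message(sprintf("dropping term '%s': single observed level", tm))
        next
      }
      forced <- ref_levels[[tm]]
      if (!is.null(forced) && forced %in% lev) {
        lev <- c(forced, setdiff(lev, forced))
      }
      refs[[tm]] <- lev[1L]
      data.table::set(dt, j = tm, value = factor(v, levels = lev))
    }
    kept <- c(kept, tm)
  }
  if (!length(kept)) {
    X <- matrix(1, nrow = length(y), dimnames = list(NULL, "(Intercept)"))
  } else {
    fml <- stats::as.formula(paste("~", paste(kept, collapse = " + ")))
    X <- stats::model.matrix(fml, data = dt)
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stopf("design matrix is rank deficient; aliased column(s): %s",
          paste(aliased, collapse = ", "))
  }

  beta <- rep(0, ncol(X))
  iter <- 0L
  max_score <- Inf
  repeat {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    score <- drop(crossprod(X, y - mu))
    max_score <- max(abs(score))
    if (max_score < tol || iter >= max_iter) break
    w <- pmax(mu * (1 - mu), 1e-12)
    fisher <- crossprod(X * w, X)
    beta <- beta + solve(fisher, score)
    iter <- iter + 1L
  }
  mu <- stats::plogis(drop(X %*% beta))
  w <- pmax(mu * (1 - mu), 1e-12)
  vcv <- solve(crossprod(X * w, X))
  se <- sqrt(diag(vcv))
  converged <- max_score < tol
  separation <- any(abs(beta) > 15)
  if (!converged) warnf("IRLS stopped at %d iterations without converging (max score %.3g)",
                        iter, max_score)
  if (separation) warnf("possible separation: coefficient(s) beyond +/-15 on the log-odds scale")

  names(beta) <- colnames(X)
  coefs <- data.table::data.table(
    term = colnames(X), estimate = unname(beta), se = unname(se),
    or = exp(unname(beta)),
    ci_low = exp(unname(beta) - 1.96 * unname(se)),
    ci_high = exp(unname(beta) + 1.96 * unname(se))
  )
  structure(
    list(coefficients = coefs, reference_levels = refs, converged = converged,
         iterations = iter, max_score = max_score, separation = separation,
         n = length(y), terms = kept, outcome = outcome),
    class = "ish_fit"
  )
}

#' @export
print.ish_fit <- function(x, ...) {
  cat(sprintf("<ish_fit> n=%d, %s after %d IRLS iterations (max score %.2g)%s\n",
              x$n, if (x$converged) "converged" else "NOT converged",
              x$iterations, x$max_score,
              if (x$separation) " [separation flagged]" else ""))
  if (length(x$reference_levels)) {
    cat("reference levels:",
        paste(sprintf("%s=%s", names(x$reference_levels), unlist(x$reference_levels)),
              collapse = ", "), "\n")
  }
  print(as.data.frame(x$coefficients), row.names = FALSE, digits = 4)
  invisible(x)
}

#' Extract a term's OR and CI from a fit
#'
#' @param fit an `ish_fit`.
#' @param pattern regular expression matched against term names.
#' @return data.table of matching coefficient rows.
#' @export
fit_terms <- function(fit, pattern) {
  fit$coefficients[grepl(pattern, term)]
}

# Exposure-group x outcome counts per stratum (the Table-2-shaped cells).
#' Cell counts of a cohort table
#'
#' @param cohort a cohort table from [build_cohort_table()] (needs
#'   `stratum`, `group`, `outcome`).
#' @return data.table with columns `stratum`, `group`, `self_harm`, `n`,
#'   including zero cells.
#' @export
cohort_cells <- function(cohort) {
  dt <- data.table::as.data.table(cohort)
  cells <- dt[, .(n = .N), by = .(stratum, group, self_harm = outcome)]
  grid <- data.table::CJ(stratum = STRATA, group = EXPOSURE_GROUPS, self_harm = 0:1)
  out <- cells[grid, on = c("stratum", "group", "self_harm")]
  out[is.na(n), n := 0L]
  data.table::setorder(out, stratum, group, -self_harm)
  out[]
}

#' Stratified prevalence, odds-ratio and adjusted-model analysis
#'
#' Runs the analysis independently inside each utilization stratum:
#' per-exposure-group prevalence, bivariable odds ratios against the
#' NEITHER reference group (Woolf intervals), and the two multivariable
#' models — minimally adjusted (age, sex, race) and fully adjusted (age,
#' sex, race, ethnicity, marital status, service connection, Charlson
#' band). Empty strata are skipped with a warning.
#'
#' @param cohort analysis table from [build_cohort_table()].
#' @param models subset of `c("bivariable", "minimal", "full")`.
#' @return list with `cells` (all strata) and one entry per non-empty
#'   stratum holding `prevalence`, `odds_ratios` and the fitted models.
#' @export
stratified_analysis <- function(cohort, models = c("bivariable", "minimal", "full")) {
  dt <- data.table::as.data.table(cohort)
  models <- match.arg(models, several.ok = TRUE)
  out <- list(cells = cohort_cells(dt))
  for (s in STRATA) {
    sub <- dt[stratum == s]
    if (nrow(sub) == 0L) {
      warnf("stratum %s is empty; skipped", s)
      next
    }
    cells <- cohort_cells(sub)[stratum == s]
    wide <- data.table::dcast(cells, group ~ self_harm, value.var = "n")
    data.table::setnames(wide, c("0", "1"), c("noncases", "cases"))
    prev <- wide[cases + noncases > 0,
                 .(group, cases, noncases,
                   prevalence = round_half_up(100 * cases / (cases + noncases), 2L))]
    ref <- wide[group == "NEITHER"]
    ors <- list()
    if ("bivariable" %in% models && nrow(ref) == 1L) {
      for (g in setdiff(EXPOSURE_GROUPS, "NEITHER")) {
        gi <- wide[group == g]
        if (nrow(gi) == 1L && gi$cases + gi$noncases > 0) {
          ors[[g]] <- odds_ratio(gi$cases, gi$noncases, ref$cases, ref$noncases)
        }
      }
    }
    fits <- list()
    for (mm in setdiff(models, "bivariable")) {
      present <- intersect(MODEL_COVARIATES[[mm]], names(sub))
      fits[[mm]] <- tryCatch(
        fit_logistic(sub, outcome = "outcome", terms = c("group", present),
                     ref_levels = list(group = "NEITHER")),
        error = function(e) {
          warnf("%s model in stratum %s failed: %s", mm, s, conditionMessage(e))
          NULL
        }
      )
    }
    out[[s]] <- list(prevalence = prev, odds_ratios = ors, fits = fits)
  }
  out
}
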