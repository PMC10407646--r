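# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `code` with the RNG seeded to `seed`, restoring the caller's RNG
#' state afterwards so seeded package functions do not perturb user code.
#'
#' @param seed integer scalar seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stopf("seed must be a single finite number, got %s", deparse(seed))
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a child seed from a base seed and a stage label, keeping the result
# inside the 32-bit integer range.
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 1103L + h) %% .Machine$integer.max)
}

#' Shift a date by whole calendar years
#'
#' Calendar-year arithmetic with day-of-month clamping: Feb 29 shifted to a
#' non-leap year becomes Feb 28. Vectorized over `dates`.
#'
#' @param dates a `Date` vector.
#' @param n integer number of years (may be negative).
#' @return a `Date` vector.
#' @export
#' @examples
#' add_years(as.Date("2016-02-29"), -5)
add_years <- function(dates, n) {
  lt <- as.POSIXlt(dates)
  lt$year <- lt$year + n
  # clamp day to the target month's length rather than rolling over
  out <- as.Date(lt)
  rolled <- !is.na(out) & (as.POSIXlt(out)$mon != lt$mon %% 12L)
  if (any(rolled)) out[rolled] <- out[rolled] - as.POSIXlt(out[rolled])$mday
  out
}

# Start of the 5-year lookback window for an index date: the window is the
# half-open interval [lookback_start(index), index).
lookback_start <- function(index_date, years = 5L) add_years(index_date, -years)

# Months since 1970-01 as an integer; used for calendar binning.
month_index <- function(dates) {
  lt <- as.POSIXlt(dates)
  (lt$year - 70L) * 12L + lt$mon
}

#' Round half away from zero
#'
#' Report-layer rounding ("half-up"): 0.125 at 2 digits gives 0.13, unlike
#' [base::round()]'s round-half-even.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector.
#' @export
round_half_up <- function(x, digits = 2L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Completed years of age at `at` for someone born on `birth`.
age_at <- function(birth, at) {
  by <- as.POSIXlt(birth)
  ay <- as.POSIXlt(at)
  age <- ay$year - by$year
  before_birthday <- (ay$mon < by$mon) | (ay$mon == by$mon & ay$mday < by$mday)
  age - as.integer(before_birthday)
}
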