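## Age- and sex-specific annual mortality. Either read from a period
## life-table CSV (age,qx_male,qx_female; the layout of SSA period tables)
## or generated synthetically from a Gompertz hazard so the package never
## needs a download.

#' Construct a life table
#'
#' @param qx_male,qx_female numeric vectors of annual death probabilities
#'   indexed by integer age 0..max_age (equal length).
#' @param force_terminal when `TRUE` (default), the final entry is forced to
#'   1 with a warning if it is not already; the table's oldest age is always
#'   certain death, and any lookup beyond `max_age` returns 1.
#' @return An object of class `dr_lifetable` with fields `max_age`,
#'   `qx_male`, `qx_female`.
#' @export
life_table <- function(qx_male, qx_female = qx_male, force_terminal = TRUE) {
  if (length(qx_male) != length(qx_female)) {
    stop("qx_male and qx_female must have equal length")
  }
  if (length(qx_male) < 1L) stop("life table must have at least one age")
  for (q in list(male = qx_male, female = qx_female)) {
    if (anyNA(q) || any(q < 0 | q > 1)) {
      bad <- which(is.na(q) | q < 0 | q > 1)[1L]
      stop("qx outside [0,1] at age ", bad - 1L)
    }
  }
  n <- length(qx_male)
  if (qx_male[n] != 1 || qx_female[n] != 1) {
    if (!force_terminal) stop("qx at max_age must be 1")
    warning("forcing qx at max_age ", n - 1L, " to 1")
    qx_male[n] <- 1
    qx_female[n] <- 1
  }
  structure(list(max_age = n - 1L, qx_male = qx_male, qx_female = qx_female),
            class = "dr_lifetable")
}

#' @export
print.dr_lifetable <- function(x, ...) {
  cat(sprintf("<dr_lifetable> ages 0-%d; qx(65, male) = %.5f\n", x$max_age,
              death_probability(x, min(65, x$max_age), TRUE)))
  invisible(x)
}

#' Load a life table from CSV
#'
#' Expected layout: header `age,qx_male,qx_female`, one row per integer age,
#' ages contiguous from 0. The final row is forced to `qx = 1` (with a
#' warning) if not already.
#'
#' @param path CSV file path.
#' @return A `dr_lifetable`.
#' @export
load_life_table <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("age", "qx_male", "qx_female")
  missing <- setdiff(need, names(x))
  if (length(missing)) {
    stop("life table is missing column(s): ", paste(missing, collapse = ", "))
  }
  if (nrow(x) == 0L) stop("life table is empty")
  expect_age <- seq.int(0L, nrow(x) - 1L)
  bad <- which(x$age != expect_age)
  if (length(bad)) {
    stop("life-table ages must be contiguous from 0; row ", bad[1L],
         " has age ", x$age[bad[1L]], " (expected ", expect_age[bad[1L]], ")")
  }
  for (col in c("qx_male", "qx_female")) {
    q <- x[[col]]
    bad <- which(is.na(q) | q < 0 | q > 1)
    if (length(bad)) {
      stop("life-table ", col, " outside [0,1] at row ", bad[1L],
           " (age ", x$age[bad[1L]], ")")
    }
  }
  life_table(x$qx_male, x$qx_female)
}

#' Write a life table to CSV
#'
#' @param table a `dr_lifetable`.
#' @param path output path.
#' @return Invisibly `path`.
#' @export
write_life_table <- function(table, path) {
  utils::write.csv(data.frame(age = 0:table$max_age,
                              qx_male = table$qx_male,
                              qx_female = table$qx_female),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Synthetic Gompertz life table
#'
#' Annual death probability `qx(age) = 1 - exp(-a * exp(b * age))`, the
#' discrete-time survival of a Gompertz hazard, clipped to [0,1]. A packaged
#' stand-in for period life tables when no CSV is supplied.
#'
#' @param a,b male baseline hazard (> 0) and slope (> 0) per year of age.
#' @param max_age oldest tabulated age (default 110); `qx` at `max_age` is
#'   set to 1.
#' @param a_female,b_female female parameters (default: same as male).
#' @return A `dr_lifetable`.
#' @export
gompertz_table <- function(a, b, max_age = 110L, a_female = a, b_female = b) {
  if (a <= 0 || a_female <= 0) stop("baseline hazard a must be > 0")
  if (b < 0 || b_female < 0) stop("slope b must be >= 0")
  ages <- 0:max_age
  qx <- function(a, b) pmin(1, pmax(0, 1 - exp(-a * exp(b * ages))))
  qm <- qx(a, b); qf <- qx(a_female, b_female)
  qm[length(qm)] <- 1
  qf[length(qf)] <- 1
  life_table(qm, qf)
}

## Default table calibration: closed-form choice of the male baseline so
## that 10-year survival from exact age 67 (death draws at ages 68..77)
## is 0.65, matching the realized survival of the source cohort (327/501).
## Slope b = 0.09/yr is a typical adult Gompertz slope. Synthetic surrogate,
## NOT SSA data. Female baseline 0.8x male (lower adult mortality).
.DEFAULT_GOMPERTZ_B <- 0.09
.default_gompertz_a <- function(target_survival = 0.65, from_age = 67L,
                                years = 10L, b = .DEFAULT_GOMPERTZ_B) {
  ages <- from_age + seq_len(years)
  -log(target_survival) / sum(exp(b * ages))
}

#' Packaged default life table
#'
#' A synthetic Gompertz table (see [gompertz_table()]) with slope 0.09/yr and
#' male baseline hazard chosen in closed form so that 10-year survival from
#' age 67 (male) is 0.65, matching the realized 10-year survival of the
#' reference cohort; the female baseline is 0.8 times the male. This is a
#' calibration surrogate for a period life table, not actuarial data.
#'
#' @param max_age oldest tabulated age (default 110).
#' @return A `dr_lifetable`.
#' @export
default_life_table <- function(max_age = 110L) {
  a <- .default_gompertz_a()
  gompertz_table(a, .DEFAULT_GOMPERTZ_B, max_age = max_age,
                 a_female = 0.8 * a, b_female = .DEFAULT_GOMPERTZ_B)
}

#' A life table with no mortality
#'
#' Useful for isolating disease transitions from death in experiments; all
#' `qx` are 0 except the terminal age.
#'
#' @param max_age oldest tabulated age (default 200, far beyond simulated
#'   ages so the terminal certainty is never reached).
#' @return A `dr_lifetable`.
#' @export
zero_mortality_table <- function(max_age = 200L) {
  qx <- rep(0, max_age + 1L)
  qx[max_age + 1L] <- 1
  life_table(qx)
}

#' Annual death probability lookup
#'
#' Returns the table's `qx` at `floor(age)` for the given sex; ages beyond
#' the table return 1.
#'
#' @param table a `dr_lifetable`.
#' @param age age(s) in years, >= 0.
#' @param male logical vector (recycled against `age`).
#' @return Numeric vector of probabilities.
#' @export
death_probability <- function(table, age, male) {
  if (!inherits(table, "dr_lifetable")) stop("table must be a dr_lifetable")
  if (anyNA(age) || any(age < 0)) stop("age must be >= 0")
  n <- max(length(age), length(male))
  age <- rep_len(floor(age), n)
  male <- rep_len(as.logical(male), n)
  idx <- pmin(age, table$max_age) + 1L
  q <- ifelse(male, table$qx_male[idx], table$qx_female[idx])
  q[age > table$max_age] <- 1
  q
}

#' Survival curve implied by a life table
#'
#' Cumulative product of `(1 - qx)` from a starting age; reaches 0 at the
#' terminal age.
#'
#' @param table a `dr_lifetable`.
#' @param from_age starting integer age.
#' @param years number of years ahead.
#' @param male sex flag.
#' @return Numeric vector of length `years`: survival to the end of each year.
#' @export
survival_curve <- function(table, from_age, years, male = TRUE) {
  q <- death_probability(table, from_age + seq_len(years), male)
  cumprod(1 - q)
}
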