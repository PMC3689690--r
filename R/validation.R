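## Cohort validation: compare a simulated cohort, variable by variable,
## against a reference cohort's summary statistics. Continuous predictors
## use a two-sample Student's t computed from summaries; dichotomous
## predictors and the NPDR/PDR split use Pearson's chi-square on the 2x2
## group-by-trait table. The criterion is NON-significance (p > 0.05): the
## simulated cohort should be statistically indistinguishable from the
## reference.

#' Two-sample t-test from summary statistics
#'
#' Pooled-variance Student's t (default) or Welch's t computed directly from
#' per-group (n, mean, sd). With zero variance in both groups, equal means
#' give t = 0, p = 1 and unequal means give infinite t, p = 0.
#'
#' @param n1,mean1,sd1 first group: size (>= 2), mean, standard deviation.
#' @param n2,mean2,sd2 second group.
#' @param pooled use the pooled-variance Student's t (default `TRUE`);
#'   `FALSE` gives Welch's t with Satterthwaite degrees of freedom.
#' @return A list: `statistic`, `df`, `p_value`, `method`.
#' @export
t_test_from_summary <- function(n1, mean1, sd1, n2, mean2, sd2,
                                pooled = TRUE) {
  if (n1 < 2 || n2 < 2) stop("both groups need n >= 2")
  if (sd1 < 0 || sd2 < 0) stop("standard deviations must be >= 0")
  diff <- mean1 - mean2
  if (sd1 == 0 && sd2 == 0) {
    t <- if (diff == 0) 0 else sign(diff) * Inf
    return(list(statistic = t, df = n1 + n2 - 2,
                p_value = if (diff == 0) 1 else 0,
                method = if (pooled) "student" else "welch"))
  }
  if (pooled) {
    df <- n1 + n2 - 2
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    method <- "student"
  } else {
    v1 <- sd1^2 / n1
    v2 <- sd2^2 / n2
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
    method <- "welch"
  }
  t <- diff / se
  list(statistic = t, df = df,
       p_value = 2 * stats::pt(-abs(t), df),
       method = method)
}

#' Pearson chi-square test on a 2x2 table
#'
#' Without continuity correction by default (Yates' correction available by
#' flag); 1 degree of freedom. A zero row or column marginal makes the
#' statistic undefined and raises an error suggesting an exact test.
#'
#' @param table 2x2 matrix of non-negative counts (group x trait).
#' @param correct apply Yates' continuity correction (default `FALSE`).
#' @return A list: `statistic`, `df`, `p_value`.
#' @export
chi_square_test <- function(table, correct = FALSE) {
  tab <- as.matrix(table)
  if (!all(dim(tab) == c(2L, 2L))) stop("table must be 2x2")
  if (any(tab < 0) || any(tab != round(tab))) {
    stop("table entries must be non-negative integer counts")
  }
  rs <- rowSums(tab); cs <- colSums(tab); N <- sum(tab)
  if (any(rs == 0) || any(cs == 0)) {
    stop("zero marginal in 2x2 table; chi-square undefined ",
         "(consider an exact test)")
  }
  expected <- outer(rs, cs) / N
  dev <- abs(tab - expected)
  if (correct) dev <- pmax(0, dev - 0.5)
  chi2 <- sum(dev^2 / expected)
  list(statistic = chi2, df = 1L,
       p_value = stats::pchisq(chi2, df = 1L, lower.tail = FALSE))
}

## The ten validated variables, in report order.
.CONTINUOUS_VARS <- c("age", "dm_duration", "bmi", "hba1c")
.DICHOT_VARS <- c("male", "hypertension", "dyslipidemia", "nephropathy",
                  "tobacco")

#' Construct a reference cohort summary
#'
#' @param n reference cohort size.
#' @param continuous named list over `age`, `dm_duration`, `bmi`, `hba1c`;
#'   each entry `c(mean, sd)`.
#' @param counts named list of positive-trait counts over `male`,
#'   `hypertension`, `dyslipidemia`, `nephropathy`, `tobacco`, plus `npdr`
#'   and `pdr` stage counts (`npdr + pdr` must equal `n`).
#' @return A `dr_reference` list.
#' @export
reference_summary <- function(n, continuous, counts) {
  n <- as.integer(n)
  if (is.na(n) || n < 2L) stop("reference n must be >= 2")
  missing <- setdiff(.CONTINUOUS_VARS, names(continuous))
  if (length(missing)) {
    stop("reference missing continuous variable(s): ",
         paste(missing, collapse = ", "))
  }
  for (k in .CONTINUOUS_VARS) {
    v <- continuous[[k]]
    if (length(v) != 2L || any(!is.finite(v)) || v[2] < 0) {
      stop("reference continuous['", k, "'] must be c(mean, sd >= 0)")
    }
  }
  missing <- setdiff(c(.DICHOT_VARS, "npdr", "pdr"), names(counts))
  if (length(missing)) {
    stop("reference missing count variable(s): ",
         paste(missing, collapse = ", "))
  }
  counts <- lapply(counts, as.integer)
  for (k in names(counts)) {
    if (is.na(counts[[k]]) || counts[[k]] < 0 || counts[[k]] > n) {
      stop("reference count '", k, "' must be within [0, n]")
    }
  }
  if (counts$npdr + counts$pdr != n) {
    stop("reference npdr + pdr counts must equal n")
  }
  structure(list(n = n, continuous = continuous[.CONTINUOUS_VARS],
                 counts = counts),
            class = "dr_reference")
}

#' Published reference summaries (training and test cohorts)
#'
#' Summary statistics of the VA eye-clinic chart-review cohort after the
#' 70/30 split: the training set (n = 351) parameterizes the generator, the
#' held-out test set (n = 150) is the validation reference. Continuous
#' variables as mean/SD, traits and stage as counts.
#'
#' @return A `dr_reference`.
#' @export
training_reference <- function() {
  reference_summary(
    n = 351L,
    continuous = list(age = c(67.5, 9.4), dm_duration = c(21.5, 9.0),
                      bmi = c(32.2, 6.3), hba1c = c(8.2, 1.8)),
    counts = list(male = 345L, hypertension = 344L, dyslipidemia = 297L,
                  nephropathy = 124L, tobacco = 88L,
                  npdr = 258L, pdr = 93L))
}

#' @rdname training_reference
#' @export
test_reference <- function() {
  reference_summary(
    n = 150L,
    continuous = list(age = c(67.3, 8.9), dm_duration = c(20.5, 8.6),
                      bmi = c(32.3, 6.8), hba1c = c(8.0, 1.5)),
    counts = list(male = 148L, hypertension = 149L, dyslipidemia = 137L,
                  nephropathy = 51L, tobacco = 25L,
                  npdr = 121L, pdr = 29L))
}

#' Summarize a cohort into a reference summary
#'
#' Computes the (n, mean, sd) and trait/stage counts of a validation-mode
#' cohort, e.g. to use one simulated cohort as the comparison reference for
#' another (the resampled-reference null of the type-I calibration checks).
#'
#' @param cohort a `dr_cohort` with all agents in NPDR or PDR.
#' @return A `dr_reference`.
#' @export
cohort_reference <- function(cohort) {
  if (!all(cohort$state %in% c("NPDR", "PDR"))) {
    stop("cohort_reference expects a validation-mode cohort")
  }
  continuous <- lapply(.CONTINUOUS_VARS, function(k)
    c(mean(cohort[[k]]), stats::sd(cohort[[k]])))
  names(continuous) <- .CONTINUOUS_VARS
  counts <- lapply(.DICHOT_VARS, function(k) sum(cohort[[k]]))
  names(counts) <- .DICHOT_VARS
  counts$npdr <- sum(cohort$state == "NPDR")
  counts$pdr <- sum(cohort$state == "PDR")
  reference_summary(nrow(cohort), continuous, counts)
}

#' Validate a simulated cohort against a reference summary
#'
#' Runs the full battery: Student's t for age, diabetes duration, BMI and
#' HbA1c; Pearson chi-square for the five dichotomous traits and the
#' NPDR/PDR stage split — ten variables in all. If both cohorts are
#' unanimous on a trait (a zero column marginal, possible for near-100%
#' traits like hypertension) the variable is recorded with statistic 0 and
#' p = 1: observed equals expected exactly, so homogeneity cannot be
#' rejected. Each variable passes when
#' its p-value exceeds `alpha` (non-significance criterion); the overall
#' flag is the conjunction. No multiple-testing adjustment is applied (each
#' variable is tested individually at `alpha`).
#'
#' @param simulated a `dr_cohort` (all agents must be in NPDR or PDR, i.e. a
#'   validation-mode cohort).
#' @param reference a `dr_reference`.
#' @param alpha per-variable significance level (default 0.05).
#' @param pooled pooled-variance Student's t (default) vs Welch.
#' @param correct Yates continuity correction for the chi-square tests
#'   (default `FALSE`).
#' @return A `dr_validation` object: data.frame with columns `variable`,
#'   `test`, `statistic`, `p_value`, `pass`, plus attributes
#'   `overall_pass` and `alpha`.
#' @export
validate_cohort <- function(simulated, reference, alpha = 0.05,
                            pooled = TRUE, correct = FALSE) {
  if (!inherits(reference, "dr_reference")) {
    stop("reference must be a dr_reference")
  }
  if (nrow(simulated) == 0L) stop("simulated cohort is empty")
  for (k in .CONTINUOUS_VARS) {
    if (is.null(reference$continuous[[k]])) {
      stop("reference is missing variable: ", k)
    }
  }
  for (k in c(.DICHOT_VARS, "npdr", "pdr")) {
    if (is.null(reference$counts[[k]])) {
      stop("reference is missing variable: ", k)
    }
  }
  n_sim <- nrow(simulated)
  rows <- list()

  for (k in .CONTINUOUS_VARS) {
    ref <- reference$continuous[[k]]
    res <- t_test_from_summary(n_sim, mean(simulated[[k]]),
                               stats::sd(simulated[[k]]),
                               reference$n, ref[1], ref[2], pooled = pooled)
    rows[[k]] <- data.frame(variable = k,
                            test = if (pooled) "t" else "welch_t",
                            statistic = res$statistic,
                            p_value = res$p_value)
  }
  for (k in .DICHOT_VARS) {
    sim_yes <- sum(simulated[[k]])
    tab <- rbind(sim = c(yes = sim_yes, no = n_sim - sim_yes),
                 ref = c(reference$counts[[k]],
                         reference$n - reference$counts[[k]]))
    if (any(colSums(tab) == 0)) {
      # both cohorts unanimous on this trait: observed equals expected
      # exactly, homogeneity cannot be rejected
      res <- list(statistic = 0, p_value = 1)
    } else {
      res <- chi_square_test(tab, correct = correct)
    }
    rows[[k]] <- data.frame(variable = k, test = "chi_square",
                            statistic = res$statistic,
                            p_value = res$p_value)
  }
  stage <- simulated$state
  if (!all(stage %in% c("NPDR", "PDR"))) {
    stop("stage validation expects a validation-mode cohort ",
         "(all agents NPDR or PDR)")
  }
  tab <- rbind(sim = c(npdr = sum(stage == "NPDR"), pdr = sum(stage == "PDR")),
               ref = c(reference$counts$npdr, reference$counts$pdr))
  res <- chi_square_test(tab, correct = correct)
  rows[["stage"]] <- data.frame(variable = "stage", test = "chi_square",
                                statistic = res$statistic,
                                p_value = res$p_value)

  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  report$pass <- report$p_value > alpha
  structure(report, class = c("dr_validation", "data.frame"),
            overall_pass = all(report$pass), alpha = alpha)
}

#' @export
print.dr_validation <- function(x, ...) {
  cat(sprintf("<dr_validation> overall %s (criterion: p > %.2f per variable)\n",
              if (attr(x, "overall_pass")) "PASS" else "FAIL",
              attr(x, "alpha")))
  out <- as.data.frame(x)
  out$statistic <- round(out$statistic, 3)
  out$p_value <- round(out$p_value, 4)
  print(out, row.names = FALSE)
  invisible(x)
}

#' Serialize a validation report to JSON
#'
#' @param report a `dr_validation`.
#' @param path optional output file.
#' @return The JSON string (invisibly when written to file).
#' @export
validation_to_json <- function(report, path = NULL) {
  obj <- list(alpha = attr(report, "alpha"),
              overall_pass = attr(report, "overall_pass"),
              variables = as.data.frame(report))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         dataframe = "rows")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(as.character(js)))
  }
  as.character(js)
}
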