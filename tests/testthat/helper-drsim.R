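# Shared fixtures, all built in code.

# A valid one-row profile with overridable fields.
fixture_profile <- function(...) {
  args <- utils::modifyList(
    list(age = 67, male = TRUE, dm_duration = 21, bmi = 32, hba1c = 8,
         hypertension = TRUE, dyslipidemia = TRUE, nephropathy = FALSE,
         tobacco = FALSE),
    list(...))
  do.call(predictor_profile, args)
}

# Config whose continuous predictors are degenerate constants, so every
# agent shares one logistic probability (frozen-predictor cohorts).
constant_config <- function(n = 100L, nephropathy_p = 0, seed = NULL, ...) {
  specs <- list(
    age = dist_spec("constant", mean = 67),
    male = dist_spec("bernoulli", p = 1),
    dm_duration = dist_spec("constant", mean = 21),
    bmi = dist_spec("constant", mean = 32),
    hba1c = dist_spec("constant", mean = 8),
    hypertension = dist_spec("bernoulli", p = 1),
    dyslipidemia = dist_spec("bernoulli", p = 1),
    nephropathy = dist_spec("bernoulli", p = nephropathy_p),
    tobacco = dist_spec("bernoulli", p = 0)
  )
  cohort_config(specs, n = n, seed = seed, ...)
}

# Config built from the held-out test cohort's own summary moments, the
# null world for validation calibration checks.
test_moment_config <- function(n = 501L, seed = NULL, ...) {
  ref <- test_reference()
  specs <- list(
    age = dist_spec("normal", mean = 67.3, sd = 8.9, lower = 21, upper = 100),
    male = dist_spec("bernoulli", p = 148 / 150),
    dm_duration = dist_spec("normal", mean = 20.5, sd = 8.6,
                            lower = 0, upper = 80),
    bmi = dist_spec("normal", mean = 32.3, sd = 6.8, lower = 12, upper = 70),
    hba1c = dist_spec("normal", mean = 8.0, sd = 1.5, lower = 4, upper = 18),
    hypertension = dist_spec("bernoulli", p = 149 / 150),
    dyslipidemia = dist_spec("bernoulli", p = 137 / 150),
    nephropathy = dist_spec("bernoulli", p = 51 / 150),
    tobacco = dist_spec("bernoulli", p = 25 / 150)
  )
  cohort_config(specs, n = n, seed = seed,
                target_pdr_prevalence = ref$counts$pdr / ref$n, ...)
}

# A uniform-mortality table: the same annual death probability q at every
# age (terminal age excepted), so mortality is age-independent.
flat_table <- function(q, max_age = 200L) {
  qx <- rep(q, max_age + 1L)
  qx[max_age + 1L] <- 1
  life_table(qx, force_terminal = FALSE)
}

# Independent logistic evaluation: plain formula, no package code.
logistic_by_hand <- function(beta, intercept, profile) {
  eta <- intercept
  for (k in names(beta)) eta <- eta + beta[[k]] * as.numeric(profile[[k]])
  1 / (1 + exp(-eta))
}
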