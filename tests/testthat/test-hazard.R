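# Logistic hazard: probability formula, intercept calibration, IRLS fit.

test_that("progression_probability matches hand evaluation of the formula", {
  zero <- logistic_hazard(c(dm_duration = 0, bmi = 0), intercept = 0)
  expect_equal(progression_probability(zero, fixture_profile()), 0.5)

  beta <- c(dm_duration = log(1.059), nephropathy = log(2.163),
            bmi = log(0.961))
  hz <- logistic_hazard(beta, intercept = -2)
  prof <- fixture_profile(dm_duration = 20, nephropathy = TRUE, bmi = 32)
  expect_equal(progression_probability(hz, prof),
               logistic_by_hand(beta, -2, prof), tolerance = 1e-12)
  expect_equal(round(progression_probability(hz, prof), 3), 0.205)

  # deep-negative intercept drives the probability to the lower tail
  tail <- logistic_hazard(beta, intercept = -500)
  expect_lt(progression_probability(tail, prof), 1e-200)
  expect_gt(progression_probability(tail, prof), 0)
})

test_that("formula agrees with brute-force evaluation on random inputs", {
  set.seed(14)
  for (i in 1:1000) {
    beta <- setNames(rnorm(3), c("dm_duration", "nephropathy", "bmi"))
    m <- rnorm(1, 0, 3)
    prof <- fixture_profile(dm_duration = runif(1, 0, 45),
                            bmi = runif(1, 15, 60),
                            nephropathy = runif(1) < 0.5)
    expect_equal(progression_probability(logistic_hazard(beta, m), prof),
                 logistic_by_hand(beta, m, prof), tolerance = 1e-12)
  }
})

test_that("probability is monotone with the sign of each coefficient", {
  hz <- calibrated_hazard(default_hazard(),
                          sample_profiles(default_config(seed = 4), 500L),
                          0.265)
  base <- fixture_profile()
  durations <- seq(0, 49, by = 1)
  p_dur <- vapply(durations, function(d)
    progression_probability(hz, fixture_profile(dm_duration = d)),
    numeric(1))
  expect_true(all(diff(p_dur) > 0))   # OR 1.059 > 1
  bmis <- seq(15, 60, by = 1)
  p_bmi <- vapply(bmis, function(b)
    progression_probability(hz, fixture_profile(bmi = b)), numeric(1))
  expect_true(all(diff(p_bmi) < 0))   # OR 0.961 < 1
  expect_gt(progression_probability(hz, fixture_profile(nephropathy = TRUE)),
            progression_probability(hz, base))
})

test_that("hazard validation catches bad coefficients and missing fields", {
  expect_error(logistic_hazard(c(0.1, 0.2)), "named")
  expect_error(logistic_hazard(c(retina_count = 1)), "unknown predictor")
  hz <- logistic_hazard(c(dm_duration = 0.1), intercept = 0)
  expect_error(progression_probability(hz, data.frame(age = 50)),
               "missing predictor")
  expect_error(
    progression_probability(logistic_hazard(c(bmi = 0.1)), fixture_profile()),
    "not calibrated")
})

test_that("calibrate_intercept has the closed-form solution for flat beta", {
  prof <- sample_profiles(default_config(seed = 9), 200L)
  zero <- c(dm_duration = 0)
  # with all coefficients zero the mean probability is plogis(m), so the
  # calibrated intercept is the logit of the target
  expect_equal(calibrate_intercept(zero, prof, 0.265),
               log(0.265 / 0.735), tolerance = 1e-8)
  expect_equal(calibrate_intercept(zero, prof, 0.5), 0, tolerance = 1e-8)
  expect_error(calibrate_intercept(zero, prof, 1.2), "inside \\(0, 1\\)")
  expect_error(calibrate_intercept(zero, prof[0, ], 0.5), "non-empty")
})

test_that("calibration inverts the mean-probability map to 1e-8", {
  set.seed(10)
  prof <- sample_profiles(default_config(), 10000L)
  hz <- default_hazard()
  for (m_true in c(-3.5, -1.02, 0, 1.7)) {
    target <- mean(progression_probability(
      logistic_hazard(hz$beta, m_true), prof))
    expect_equal(calibrate_intercept(hz$beta, prof, target), m_true,
                 tolerance = 1e-8)
  }
  # post-condition: achieved mean equals the target
  m <- calibrate_intercept(hz$beta, prof, 0.265)
  expect_equal(mean(progression_probability(logistic_hazard(hz$beta, m),
                                            prof)),
               0.265, tolerance = 1e-8)
})

test_that("fit_logistic rejects degenerate designs", {
  y <- rep(c(0, 1), 20)
  expect_error(fit_logistic(y, data.frame(x = rep(0, 40))), "singular")
  expect_error(fit_logistic(rep(1, 40), data.frame(x = rnorm(40))),
               "both values")
  expect_error(fit_logistic(y, data.frame(a = 1:40, b = 2 * (1:40))),
               "singular")
})

test_that("fit on a single binary covariate equals the cross-product ratio", {
  # 2x2-collapsible data: fitted OR must equal ad/bc exactly (saturated MLE)
  a <- 30; b <- 70; c <- 15; d <- 85   # exposed: a cases, b controls; etc.
  y <- c(rep(1, a), rep(0, b), rep(1, c), rep(0, d))
  x <- c(rep(1, a + b), rep(0, c + d))
  fit <- fit_logistic(y, data.frame(exposed = x))
  expect_equal(unname(fit$odds_ratios["exposed"]), (a * d) / (b * c),
               tolerance = 1e-8)
  expect_true(fit$converged)
})

test_that("IRLS agrees with the glm reference implementation", {
  set.seed(31)
  n <- 4000L
  X <- data.frame(dur = rnorm(n, 20, 9), neph = rbinom(n, 1, 0.35),
                  bmi = rnorm(n, 32, 6))
  eta <- -1.5 + 0.057 * X$dur + 0.77 * X$neph - 0.04 * X$bmi
  y <- rbinom(n, 1, plogis(eta))
  fit <- fit_logistic(y, X)
  ref <- glm(y ~ dur + neph + bmi, data = cbind(X, y = y),
             family = binomial())
  expect_equal(unname(fit$intercept), unname(coef(ref)[1]),
               tolerance = 1e-7)
  expect_equal(fit$coefficients, coef(ref)[-1], tolerance = 1e-7)
  expect_equal(unname(fit$se),
               unname(summary(ref)$coefficients[-1, "Std. Error"]),
               tolerance = 1e-5)
  expect_equal(fit$loglik, as.numeric(logLik(ref)), tolerance = 1e-8)
  # Wald CI construction on the odds-ratio scale
  expect_equal(fit$ci95[, "low"],
               exp(fit$coefficients - qnorm(0.975) * fit$se),
               tolerance = 1e-12)
})

test_that("perfect separation is reported, not silently returned", {
  y <- c(rep(0, 20), rep(1, 20))
  x <- c(rnorm(20, -5), rnorm(20, 5))
  expect_warning(fit <- fit_logistic(y, data.frame(x = x)), "separation")
  expect_false(fit$converged)
})

test_that("recovery experiment recovers the published odds ratios", {
  fit <- recovery_experiment(n = 100000L, seed = 2024L)
  truth <- exp(attr(fit, "truth")$beta)
  expect_equal(unname(truth),
               c(1.059, 2.163, 0.961), tolerance = 1e-12)
  for (k in names(truth)) {
    expect_lt(abs(fit$odds_ratios[[k]] - truth[[k]]) / truth[[k]], 0.02)
    expect_gt(truth[[k]], fit$ci95[k, "low"])
    expect_lt(truth[[k]], fit$ci95[k, "high"])
  }
  expect_true(fit$converged)
})

test_that("fit results serialize to JSON with CIs and metadata", {
  fit <- recovery_experiment(n = 4000L, seed = 5L)
  path <- withr::local_tempfile(fileext = ".json")
  fit_to_json(fit, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$odds_ratios$dm_duration,
               unname(fit$odds_ratios["dm_duration"]))
  expect_true(back$converged)
  expect_named(back$ci95$bmi, c("low", "high"))
})
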