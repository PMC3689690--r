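## Synthetic cohort generation. The source cohort survives only as summary
## moments (mean/SD per continuous predictor, prevalence per flag), so
## predictors are sampled from moment-parameterized families — truncated
## normal by default, with lognormal and gamma available — and initial DR
## stage is assigned from the calibrated logistic predicted probabilities.

#' Distribution specification for one predictor
#'
#' @param family one of `"normal"`, `"lognormal"`, `"gamma"`, `"bernoulli"`,
#'   `"constant"`. The lognormal and gamma families are moment-matched to
#'   the given mean and SD.
#' @param mean,sd mean and standard deviation (sd ignored for bernoulli and
#'   constant).
#' @param lower,upper optional truncation bounds; sampling rejects draws
#'   outside them.
#' @param p success probability (bernoulli only).
#' @return A `dr_dist_spec` list.
#' @export
dist_spec <- function(family = c("normal", "lognormal", "gamma", "bernoulli",
                                 "constant"),
                      mean = NULL, sd = NULL, lower = -Inf, upper = Inf,
                      p = NULL) {
  choices <- c("normal", "lognormal", "gamma", "bernoulli", "constant")
  if (length(family) > 1L) family <- family[1L]
  if (!is.character(family) || !family %in% choices) {
    stop("unknown distribution family '", paste(family, collapse = ","),
         "' (must be one of ", paste(choices, collapse = ", "), ")")
  }
  if (is.finite(lower) && is.finite(upper) && lower >= upper) {
    stop("truncation bounds require lower < upper")
  }
  if (family == "bernoulli") {
    if (is.null(p) || !is.finite(p) || p < 0 || p > 1) {
      stop("bernoulli spec requires p in [0,1]")
    }
  } else if (family == "constant") {
    if (is.null(mean) || !is.finite(mean)) stop("constant spec requires mean")
  } else {
    if (is.null(mean) || is.null(sd) || !is.finite(mean) || !is.finite(sd) ||
        sd < 0) {
      stop(family, " spec requires finite mean and sd >= 0")
    }
    if (family %in% c("lognormal", "gamma") && (mean <= 0 || sd <= 0)) {
      stop(family, " spec requires positive mean and sd")
    }
  }
  structure(list(family = family, mean = mean, sd = sd,
                 lower = lower, upper = upper, p = p),
            class = "dr_dist_spec")
}

## Maximum resampling rounds before declaring the bounds infeasible.
.MAX_REJECTIONS <- 1000L

## One untruncated draw batch from the spec's family.
.raw_draw <- function(spec, n) {
  switch(spec$family,
    normal = stats::rnorm(n, spec$mean, spec$sd),
    lognormal = {
      sdlog2 <- log(1 + (spec$sd / spec$mean)^2)
      stats::rlnorm(n, meanlog = log(spec$mean) - sdlog2 / 2,
                    sdlog = sqrt(sdlog2))
    },
    gamma = stats::rgamma(n, shape = (spec$mean / spec$sd)^2,
                          rate = spec$mean / spec$sd^2),
    bernoulli = stats::runif(n) < spec$p,
    constant = rep(spec$mean, n)
  )
}

#' Sample from a distribution specification
#'
#' Continuous draws outside `[lower, upper]` are rejected and redrawn; more
#' than 1000 consecutive fully-rejected resampling rounds raise a
#' configuration error (infeasible bounds).
#'
#' @param spec a `dr_dist_spec`.
#' @param n number of draws.
#' @return Numeric (or logical, for bernoulli) vector of length `n`.
#' @export
sample_dist <- function(spec, n) {
  x <- .raw_draw(spec, n)
  if (spec$family %in% c("bernoulli", "constant")) {
    if (spec$family == "constant" &&
        (spec$mean < spec$lower || spec$mean > spec$upper)) {
      stop("constant value ", spec$mean, " outside truncation bounds")
    }
    return(x)
  }
  bad <- which(x < spec$lower | x > spec$upper)
  rounds <- 0L
  while (length(bad)) {
    rounds <- rounds + 1L
    if (rounds > .MAX_REJECTIONS) {
      stop("infeasible truncation bounds for ", spec$family,
           " spec (", .MAX_REJECTIONS, " consecutive rejection rounds)")
    }
    x[bad] <- .raw_draw(spec, length(bad))
    bad <- bad[x[bad] < spec$lower | x[bad] > spec$upper]
  }
  x
}

#' Mean of a truncated-normal specification
#'
#' Closed form `mu + sigma * (phi(a) - phi(b)) / (Phi(b) - Phi(a))` with
#' standardized bounds a, b; used as an oracle for moment-recovery checks
#' and handy when configuring generators to hit a target sample mean.
#'
#' @param spec a normal-family `dr_dist_spec`.
#' @return The truncated mean.
#' @export
truncated_normal_mean <- function(spec) {
  stopifnot(spec$family == "normal")
  a <- (spec$lower - spec$mean) / spec$sd
  b <- (spec$upper - spec$mean) / spec$sd
  spec$mean + spec$sd * (stats::dnorm(a) - stats::dnorm(b)) /
    (stats::pnorm(b) - stats::pnorm(a))
}

#' Cohort configuration
#'
#' Bundles everything needed to generate and simulate a cohort: one
#' distribution spec per predictor, the cohort size, the constant transition
#' rates, the logistic hazard (intercept possibly `NA`, to be calibrated),
#' the calibration target, and the seed.
#'
#' @param specs named list of `dr_dist_spec`, one per predictor field
#'   (`age`, `male`, `dm_duration`, `bmi`, `hba1c`, `hypertension`,
#'   `dyslipidemia`, `nephropathy`, `tobacco`).
#' @param n cohort size (>= 1).
#' @param rates named list: `onset_annual` (NO_DR to NPDR, default 0.077),
#'   `vl_annual` (PDR to VL, default 0.007), `entrant_no_dr` (probability a
#'   new entrant starts without retinopathy, default 0.715), `prp_annual`
#'   (PDR back to NPDR via pan-retinal photocoagulation, default 0).
#' @param hazard a `dr_hazard` (default [default_hazard()], intercept `NA`).
#' @param target_pdr_prevalence calibration target for the intercept
#'   (default 0.265, the training-cohort PDR prevalence).
#' @param hazard_scale multiplier applied to the annual NPDR-to-PDR
#'   probability in the engine (default 1; see the methods vignette on the
#'   prevalence-as-hazard reuse this exposes).
#' @param record_history record per-agent (year, state) change history
#'   during simulation (default `FALSE`).
#' @param seed integer seed, or `NULL`.
#' @return A `dr_config` list.
#' @export
cohort_config <- function(specs, n = 501L, rates = list(),
                          hazard = default_hazard(),
                          target_pdr_prevalence = 0.265,
                          hazard_scale = 1.0,
                          record_history = FALSE,
                          seed = NULL) {
  missing <- setdiff(.PROFILE_FIELDS, names(specs))
  if (length(missing)) {
    stop("specs missing predictor(s): ", paste(missing, collapse = ", "))
  }
  for (k in names(specs)) {
    if (!inherits(specs[[k]], "dr_dist_spec")) {
      stop("specs[['", k, "']] is not a dr_dist_spec")
    }
  }
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("cohort size n must be >= 1")
  defaults <- list(onset_annual = 0.077, vl_annual = 0.007,
                   entrant_no_dr = 0.715, prp_annual = 0.0)
  unknown <- setdiff(names(rates), names(defaults))
  if (length(unknown)) {
    stop("unknown rate(s): ", paste(unknown, collapse = ", "))
  }
  rates <- utils::modifyList(defaults, rates)
  for (k in names(rates)) {
    v <- rates[[k]]
    if (!is.numeric(v) || !is.finite(v) || v < 0 || v > 1) {
      stop("rate '", k, "' must be a probability in [0,1]")
    }
  }
  if (!inherits(hazard, "dr_hazard")) stop("hazard must be a dr_hazard")
  if (!is.finite(target_pdr_prevalence) || target_pdr_prevalence <= 0 ||
      target_pdr_prevalence >= 1) {
    stop("target_pdr_prevalence must be inside (0,1)")
  }
  if (!is.finite(hazard_scale) || hazard_scale < 0) {
    stop("hazard_scale must be >= 0")
  }
  structure(list(specs = specs[.PROFILE_FIELDS], n = n, rates = rates,
                 hazard = hazard,
                 target_pdr_prevalence = target_pdr_prevalence,
                 hazard_scale = hazard_scale,
                 record_history = isTRUE(record_history),
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "dr_config")
}

#' Default configuration: the training-cohort summary statistics
#'
#' Moment-parameterized truncated-normal specs for the continuous predictors
#' and Bernoulli prevalences for the flags, taken from the training column
#' of the published cohort summary (n = 351): age 67.5 +/- 9.4 yr, diabetes
#' duration 21.5 +/- 9.0 yr, BMI 32.2 +/- 6.3, HbA1c 8.2 +/- 1.8%; male
#' 98.3%, hypertension 98.0%, dyslipidemia 84.3%, nephropathy 35.3%,
#' tobacco use 25.1%. Truncation bounds: age [21, 100], duration [0, 80],
#' BMI [12, 70], HbA1c [4, 18].
#'
#' @param n cohort size (default 501, the replicated cohort size).
#' @param seed integer seed or `NULL`.
#' @param ... further arguments passed to [cohort_config()].
#' @return A `dr_config`.
#' @export
default_config <- function(n = 501L, seed = NULL, ...) {
  specs <- list(
    age = dist_spec("normal", mean = 67.5, sd = 9.4, lower = 21, upper = 100),
    male = dist_spec("bernoulli", p = 0.983),
    dm_duration = dist_spec("normal", mean = 21.5, sd = 9.0,
                            lower = 0, upper = 80),
    bmi = dist_spec("normal", mean = 32.2, sd = 6.3, lower = 12, upper = 70),
    hba1c = dist_spec("normal", mean = 8.2, sd = 1.8, lower = 4, upper = 18),
    hypertension = dist_spec("bernoulli", p = 0.980),
    dyslipidemia = dist_spec("bernoulli", p = 0.843),
    nephropathy = dist_spec("bernoulli", p = 0.353),
    tobacco = dist_spec("bernoulli", p = 0.251)
  )
  cohort_config(specs, n = n, seed = seed, ...)
}

#' @export
print.dr_config <- function(x, ...) {
  cat(sprintf("<dr_config> n = %d, seed = %s\n", x$n,
              if (is.null(x$seed)) "NULL" else x$seed))
  cat("  rates:",
      paste(sprintf("%s=%g", names(x$rates), unlist(x$rates)),
            collapse = "  "), "\n")
  cat("  hazard ORs:",
      paste(sprintf("%s=%.4g", names(x$hazard$beta), exp(x$hazard$beta)),
            collapse = "  "),
      sprintf(" target PDR prevalence %.3f\n", x$target_pdr_prevalence))
  invisible(x)
}

#' Sample predictor profiles from a configuration
#'
#' Each predictor is drawn from its configured family with rejection against
#' its truncation bounds; the joint constraint `dm_duration <= age - 18` is
#' then enforced by resampling `dm_duration` for offending rows (up to 1000
#' rounds, after which the configuration is declared infeasible).
#'
#' @param config a `dr_config`.
#' @param n number of profiles (default `config$n`).
#' @return A data.frame of `n` valid profiles.
#' @export
sample_profiles <- function(config, n = config$n) {
  if (!inherits(config, "dr_config")) stop("config must be a dr_config")
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("number of profiles must be >= 1")
  prof <- data.frame(row.names = seq_len(n))
  for (k in .PROFILE_FIELDS) {
    x <- sample_dist(config$specs[[k]], n)
    prof[[k]] <- if (k %in% .FLAG_FIELDS) as.logical(x) else as.numeric(x)
  }
  cap <- prof$age - 18
  bad <- which(prof$dm_duration > cap)
  rounds <- 0L
  while (length(bad)) {
    rounds <- rounds + 1L
    if (rounds > .MAX_REJECTIONS) {
      stop("infeasible joint constraint dm_duration <= age - 18 ",
           "(check the age and dm_duration specs)")
    }
    prof$dm_duration[bad] <- sample_dist(config$specs$dm_duration,
                                         length(bad))
    bad <- bad[prof$dm_duration[bad] > cap[bad]]
  }
  validate_profile(prof)
  prof
}

#' Assign initial DR stage from logistic predicted probabilities
#'
#' In validation-replica mode (`include_no_dr = FALSE`, matching a cohort
#' restricted to patients already carrying a DR diagnosis) each agent is
#' PDR with its predicted probability and NPDR otherwise. In steady-state
#' mode (`include_no_dr = TRUE`) the agent is first NO_DR with probability
#' `no_dr_prob`; the remainder are split NPDR/PDR the same way.
#'
#' @param profile predictor profile(s).
#' @param hazard a calibrated `dr_hazard`.
#' @param include_no_dr allow the no-retinopathy state.
#' @param no_dr_prob probability of NO_DR when included (default 0.715, the
#'   population fraction of diabetic adults without retinopathy).
#' @return Character vector of state names, one per profile row.
#' @export
assign_initial_stage <- function(profile, hazard, include_no_dr = FALSE,
                                 no_dr_prob = 0.715) {
  n <- nrow(profile)
  p <- progression_probability(hazard, profile)
  state <- rep("NPDR", n)
  if (include_no_dr) {
    if (!is.finite(no_dr_prob) || no_dr_prob < 0 || no_dr_prob > 1) {
      stop("no_dr_prob must be in [0,1]")
    }
    no_dr <- stats::runif(n) < no_dr_prob
  } else {
    no_dr <- rep(FALSE, n)
  }
  pdr <- stats::runif(n) < p
  state[pdr] <- "PDR"
  state[no_dr] <- "NO_DR"
  state
}

#' Generate a synthetic cohort
#'
#' Samples `config$n` predictor profiles, calibrates the hazard intercept to
#' the configured PDR prevalence target on those profiles (unless the
#' intercept is already finite), assigns initial stages, and returns the
#' assembled cohort. Fully reproducible given `config$seed`.
#'
#' @param config a `dr_config`.
#' @param mode `"validation"` (default; no-retinopathy state uninhabited,
#'   replicating a cohort of diagnosed patients) or `"steady_state"`
#'   (entrant-style assignment including NO_DR with the configured
#'   `entrant_no_dr` probability).
#' @param year entry year stamped on the agents (default 0).
#' @return A `dr_cohort` of `config$n` agents with ids `1..n`; the
#'   calibrated hazard is attached as attribute `"hazard"`.
#' @export
generate_cohort <- function(config, mode = c("validation", "steady_state"),
                            year = 0L) {
  mode <- match.arg(mode)
  if (!inherits(config, "dr_config")) stop("config must be a dr_config")
  if (!is.null(config$seed)) set.seed(config$seed)
  prof <- sample_profiles(config, config$n)
  hz <- config$hazard
  if (!is.finite(hz$intercept)) {
    hz <- calibrated_hazard(hz, prof, config$target_pdr_prevalence)
  }
  state <- assign_initial_stage(prof, hz,
                                include_no_dr = (mode == "steady_state"),
                                no_dr_prob = config$rates$entrant_no_dr)
  cohort <- cbind(data.frame(id = seq_len(config$n)), prof,
                  data.frame(state = state, entry_year = as.integer(year)))
  history <- if (config$record_history) {
    data.frame(id = cohort$id, year = as.integer(year), state = state)
  } else NULL
  out <- as_dr_cohort(cohort, history = history)
  attr(out, "hazard") <- hz
  out
}

#' Emulate the chart-abstraction and train/test-split pipeline
#'
#' Generates `n_total` synthetic chart records, marks `n_missing_duration`
#' of them (chosen at random) as having undeterminable diabetes duration,
#' excludes those, and randomly splits the retained records 70/30 into
#' training and test sets. With the reference numbers (535 records, 34
#' missing) this reproduces the 501 retained records and the 351/150 split.
#'
#' @param n_total number of abstracted records (default 535).
#' @param n_missing_duration records with missing duration (default 34; must
#'   be < `n_total`).
#' @param config generating configuration (default [default_config()]).
#' @param train_fraction fraction of retained records assigned to training
#'   (default 0.7; training size is `round(train_fraction * n_retained)`).
#' @return A list: `records` (all `n_total`, with `missing_duration` flag and
#'   `dm_duration` set `NA` where missing), `retained`, `train`, `test`
#'   (data.frames of records).
#' @export
generate_abstraction_fixture <- function(n_total = 535L,
                                         n_missing_duration = 34L,
                                         config = default_config(),
                                         train_fraction = 0.7) {
  n_total <- as.integer(n_total)
  n_missing <- as.integer(n_missing_duration)
  if (n_missing >= n_total) {
    stop("n_missing_duration must be < n_total (no records would remain)")
  }
  if (n_missing < 0L) stop("n_missing_duration must be >= 0")
  prof <- sample_profiles(config, n_total)
  hz <- config$hazard
  if (!is.finite(hz$intercept)) {
    hz <- calibrated_hazard(hz, prof, config$target_pdr_prevalence)
  }
  records <- cbind(data.frame(record = seq_len(n_total)), prof)
  records$stage <- assign_initial_stage(prof, hz)
  records$missing_duration <- FALSE
  miss <- sample.int(n_total, n_missing)
  records$missing_duration[miss] <- TRUE
  records$dm_duration[miss] <- NA_real_
  retained <- records[!records$missing_duration, , drop = FALSE]
  n_ret <- nrow(retained)
  n_train <- as.integer(round(train_fraction * n_ret))
  idx <- sample.int(n_ret, n_train)
  list(records = records,
       retained = retained,
       train = retained[idx, , drop = FALSE],
       test = retained[-idx, , drop = FALSE])
}
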