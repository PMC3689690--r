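## Simulation driver. Each simulated year every living agent executes the
## annual 'event':
##   (1) age and diabetes duration increase by one;
##   (2) a mortality draw against qx(new age, sex) may move the agent to
##       DEATH;
##   (3) survivors take one state-specific advancement draw (fresh uniform
##       u, advance iff u < p): NO_DR -> NPDR at the constant onset rate;
##       NPDR -> PDR at the agent's logistic predicted probability (times
##       the configured hazard scale); PDR -> VL at the constant vision-loss
##       rate;
##   (4) agents that began the year in PDR and are still PDR take a PRP draw
##       reverting to NPDR with the configured annual probability.
## Only age and dm_duration evolve; BMI, HbA1c and the comorbidity flags
## stay fixed. The ordering (increment -> death -> progression -> PRP)
## ensures mortality uses the updated age and at most one state transition
## occurs per agent-year.

#' Apply one annual event to living agents
#'
#' Vectorized over the rows of `cohort`; all agents must be alive. Uniform
#' draws are consumed in a fixed documented order (one mortality draw per
#' agent in row order, then one advancement draw per survivor, then one PRP
#' draw per continuing PDR agent), so results are reproducible under a
#' seeded RNG.
#'
#' @param cohort a `dr_cohort` of living agents.
#' @param hazard a calibrated `dr_hazard` for the NPDR-to-PDR transition.
#' @param rates transition-rate list (see [cohort_config()]).
#' @param table a `dr_lifetable`.
#' @param hazard_scale multiplier on the annual NPDR-to-PDR probability
#'   (default 1).
#' @return The cohort after one year (same rows, updated `age`,
#'   `dm_duration`, `state`).
#' @export
annual_event <- function(cohort, hazard, rates, table, hazard_scale = 1.0) {
  if (any(cohort$state == "DEATH")) {
    stop("annual_event received dead agent(s); filter to living agents")
  }
  n <- nrow(cohort)
  if (n == 0L) return(cohort)

  cohort$age <- cohort$age + 1
  cohort$dm_duration <- cohort$dm_duration + 1

  qx <- death_probability(table, cohort$age, cohort$male)
  dies <- stats::runif(n) < qx
  state <- cohort$state
  state_before <- state
  state[dies] <- "DEATH"

  live <- which(!dies)
  if (length(live)) {
    u <- stats::runif(length(live))
    s <- state[live]
    p <- numeric(length(live))
    p[s == "NO_DR"] <- rates$onset_annual
    npdr <- s == "NPDR"
    if (any(npdr)) {
      p[npdr] <- pmin(1, hazard_scale *
                        progression_probability(
                          hazard, cohort[live[npdr], , drop = FALSE]))
    }
    p[s == "PDR"] <- rates$vl_annual
    advance <- u < p
    s[advance & state[live] == "NO_DR"] <- "NPDR"
    s[advance & state[live] == "NPDR"] <- "PDR"
    s[advance & state[live] == "PDR"] <- "VL"
    state[live] <- s

    if (rates$prp_annual > 0) {
      prp_pool <- live[state_before[live] == "PDR" & state[live] == "PDR"]
      if (length(prp_pool)) {
        revert <- stats::runif(length(prp_pool)) < rates$prp_annual
        state[prp_pool[revert]] <- "NPDR"
      }
    }
  }
  check_transition(state_before, state)
  cohort$state <- state
  cohort
}

#' Add new entrants to a cohort
#'
#' Each entrant starts without retinopathy with probability
#' `rates$entrant_no_dr` (default 0.715); the remainder are assigned
#' NPDR or PDR from their logistic predicted probability.
#'
#' @param cohort existing `dr_cohort`.
#' @param n_new number of entrants (>= 0).
#' @param config a `dr_config` supplying the predictor distributions and
#'   rates.
#' @param year simulation year stamped as the entrants' `entry_year`.
#' @param hazard a calibrated `dr_hazard`; default: the hazard attached to
#'   the cohort by [generate_cohort()].
#' @return The cohort with `n_new` appended agents (fresh ids continuing
#'   from the current maximum).
#' @export
add_entrants <- function(cohort, n_new, config, year,
                         hazard = attr(cohort, "hazard")) {
  n_new <- as.integer(n_new)
  if (is.na(n_new) || n_new < 0L) stop("n_new must be >= 0")
  if (n_new == 0L) return(cohort)
  if (is.null(hazard)) stop("a calibrated hazard is required for entrants")
  prof <- sample_profiles(config, n_new)
  state <- assign_initial_stage(prof, hazard, include_no_dr = TRUE,
                                no_dr_prob = config$rates$entrant_no_dr)
  ids <- max(cohort$id, 0L) + seq_len(n_new)
  new <- cbind(data.frame(id = as.integer(ids)), prof,
               data.frame(state = state, entry_year = as.integer(year)))
  history <- attr(cohort, "history")
  if (!is.null(history)) {
    history <- rbind(history, data.frame(id = new$id, year = as.integer(year),
                                         state = state))
  }
  hz <- attr(cohort, "hazard")
  out <- as_dr_cohort(rbind(as.data.frame(cohort), new), history = history)
  attr(out, "hazard") <- hz
  out
}

#' Run a multi-year cohort simulation
#'
#' Generates the initial cohort from `config`, then for each year applies
#' the annual event to every living agent and appends any new entrants.
#' Yearly state tallies cover every agent ever entered (the dead remain
#' tallied under `DEATH`), so counts always sum to the number entered.
#'
#' @param config a `dr_config`; `config$seed` (or the `seed` argument)
#'   drives all randomness.
#' @param years number of simulated years (>= 0).
#' @param entrants_per_year new agents added at the end of each year
#'   (default 0, matching a closed-cohort run).
#' @param mode initial-stage mode passed to [generate_cohort()].
#' @param table a `dr_lifetable` (default [default_life_table()]).
#' @param seed overrides `config$seed` when given.
#' @return A `dr_simulation` list: `yearly_counts` (data.frame, one row per
#'   year 0..years with the five state counts), `final_cohort`,
#'   `survivor_summary`, `deceased_summary`, `history` (or `NULL`), `seed`,
#'   `years`, `config` (echo).
#' @export
run_simulation <- function(config, years = 10L, entrants_per_year = 0L,
                           mode = c("validation", "steady_state"),
                           table = default_life_table(), seed = NULL) {
  mode <- match.arg(mode)
  years <- as.integer(years)
  if (is.na(years) || years < 0L) stop("years must be >= 0")
  if (!is.null(seed)) config$seed <- as.integer(seed)
  cohort <- generate_cohort(config, mode = mode, year = 0L)
  hz <- attr(cohort, "hazard")

  counts <- matrix(0L, nrow = years + 1L, ncol = length(DR_STATES),
                   dimnames = list(NULL, DR_STATES))
  counts[1L, ] <- state_counts(cohort)
  history <- attr(cohort, "history")

  for (yr in seq_len(years)) {
    alive <- cohort$state != "DEATH"
    if (any(alive)) {
      before <- cohort$state[alive]
      stepped <- annual_event(cohort[alive, , drop = FALSE], hz,
                              config$rates, table, config$hazard_scale)
      cohort[alive, ] <- stepped
      if (!is.null(history)) {
        changed <- before != stepped$state
        if (any(changed)) {
          history <- rbind(history,
                           data.frame(id = stepped$id[changed],
                                      year = yr,
                                      state = stepped$state[changed]))
        }
      }
    }
    if (entrants_per_year > 0L) {
      attr(cohort, "history") <- history
      cohort <- add_entrants(cohort, entrants_per_year, config, yr,
                             hazard = hz)
      history <- attr(cohort, "history")
    }
    counts[yr + 1L, ] <- state_counts(cohort)
  }
  attr(cohort, "history") <- history

  groups <- summarize_groups(cohort)
  structure(list(yearly_counts = cbind(data.frame(year = 0:years),
                                       as.data.frame(counts)),
                 final_cohort = cohort,
                 survivor_summary = groups$survivors,
                 deceased_summary = groups$deceased,
                 history = history,
                 seed = config$seed,
                 years = years,
                 config = config),
            class = "dr_simulation")
}

#' @export
print.dr_simulation <- function(x, ...) {
  last <- x$yearly_counts[nrow(x$yearly_counts), ]
  cat(sprintf("<dr_simulation> %d years, %d agents entered\n",
              x$years, nrow(x$final_cohort)))
  cat("  final counts:",
      paste(sprintf("%s=%d", DR_STATES, unlist(last[DR_STATES])),
            collapse = "  "), "\n")
  if (!is.na(x$survivor_summary$mean_age)) {
    cat(sprintf("  survivors: n=%d mean age %.1f, duration %.1f\n",
                x$survivor_summary$n, x$survivor_summary$mean_age,
                x$survivor_summary$mean_dm_duration))
  }
  if (!is.na(x$deceased_summary$mean_age)) {
    cat(sprintf("  deceased:  n=%d mean age %.1f, duration %.1f\n",
                x$deceased_summary$n, x$deceased_summary$mean_age,
                x$deceased_summary$mean_dm_duration))
  }
  invisible(x)
}

.group_summary <- function(group) {
  if (nrow(group) == 0L) {
    return(list(n = 0L, mean_age = NA_real_, mean_dm_duration = NA_real_,
                state_counts = state_counts(group)))
  }
  list(n = nrow(group),
       mean_age = mean(group$age),
       mean_dm_duration = mean(group$dm_duration),
       state_counts = state_counts(group))
}

#' Summarize a cohort by survival status
#'
#' Deceased agents' ages and durations are their values at death (the
#' annual event stops updating an agent once it enters `DEATH`).
#'
#' @param x a `dr_cohort` or a `dr_simulation` (its final cohort is used).
#' @return A list with `survivors` and `deceased`, each holding `n`,
#'   `mean_age`, `mean_dm_duration` (NA when the group is empty) and
#'   `state_counts`.
#' @export
summarize_groups <- function(x) {
  cohort <- if (inherits(x, "dr_simulation")) x$final_cohort else x
  dead <- cohort$state == "DEATH"
  list(survivors = .group_summary(cohort[!dead, , drop = FALSE]),
       deceased = .group_summary(cohort[dead, , drop = FALSE]))
}

#' Serialize a simulation result to JSON
#'
#' Writes the yearly counts, group summaries, seed and a configuration echo;
#' the final cohort itself is written separately as CSV (see
#' [write_cohort()]).
#'
#' @param result a `dr_simulation`.
#' @param path optional output file.
#' @return The JSON string (invisibly when written to file).
#' @export
simulation_to_json <- function(result, path = NULL) {
  cfg <- result$config
  obj <- list(
    years = result$years,
    seed = result$seed,
    yearly_counts = result$yearly_counts,
    survivor_summary = result$survivor_summary[c("n", "mean_age",
                                                 "mean_dm_duration")],
    deceased_summary = result$deceased_summary[c("n", "mean_age",
                                                 "mean_dm_duration")],
    survivor_state_counts = as.list(result$survivor_summary$state_counts),
    deceased_state_counts = as.list(result$deceased_summary$state_counts),
    config = list(n = cfg$n, rates = cfg$rates,
                  hazard = list(beta = as.list(cfg$hazard$beta),
                                intercept = cfg$hazard$intercept),
                  target_pdr_prevalence = cfg$target_pdr_prevalence,
                  hazard_scale = cfg$hazard_scale,
                  seed = cfg$seed)
  )
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         dataframe = "rows", na = "null")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(as.character(js)))
  }
  as.character(js)
}

#' Analytic one-year transition matrix for frozen predictors
#'
#' For an agent whose predictors (hence logistic probability `p`) and
#' annual death probability `q` are constant, one simulated year is a
#' five-state Markov step. This closed-form matrix is the brute-force
#' oracle for engine equivalence tests: the simulated state distribution
#' after `k` years must match the initial distribution times the k-th
#' matrix power.
#'
#' @param p annual NPDR-to-PDR probability.
#' @param q annual death probability.
#' @param rates transition-rate list (see [cohort_config()]).
#' @return A 5x5 row-stochastic matrix over [DR_STATES].
#' @export
transition_matrix <- function(p, q, rates) {
  s <- DR_STATES
  M <- matrix(0, 5, 5, dimnames = list(s, s))
  on <- rates$onset_annual; vl <- rates$vl_annual; pr <- rates$prp_annual
  M["NO_DR", ] <- c((1 - q) * (1 - on), (1 - q) * on, 0, 0, q)
  M["NPDR", ]  <- c(0, (1 - q) * (1 - p), (1 - q) * p, 0, q)
  M["PDR", ]   <- c(0, (1 - q) * (1 - vl) * pr,
                    (1 - q) * (1 - vl) * (1 - pr), (1 - q) * vl, q)
  M["VL", ]    <- c(0, 0, 0, 1 - q, q)
  M["DEATH", ] <- c(0, 0, 0, 0, 1)
  M
}
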