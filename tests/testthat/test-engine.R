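# Simulation engine: the annual event, entrants, multi-year runs, and the
# analytic Markov-chain oracle.

no_death <- zero_mortality_table()

frozen_hazard <- function(p) {
  # constant-profile hazard achieving exactly probability p for the
  # constant_config profile (all coefficients zero)
  logistic_hazard(c(dm_duration = 0), intercept = qlogis(p))
}

rates_of <- function(...) {
  utils::modifyList(list(onset_annual = 0.077, vl_annual = 0.007,
                         entrant_no_dr = 0.715, prp_annual = 0), list(...))
}

one_agent_cohort <- function(state, ...) {
  reset_agent_ids()
  make_agent(fixture_profile(...), state, 0L)
}

test_that("certain and impossible transitions behave deterministically", {
  set.seed(1)
  a <- annual_event(one_agent_cohort("NO_DR"), frozen_hazard(0.5),
                    rates_of(onset_annual = 1), no_death)
  expect_identical(a$state, "NPDR")

  b0 <- one_agent_cohort("PDR")
  b <- annual_event(b0, frozen_hazard(1e-12), rates_of(vl_annual = 0),
                    no_death)
  expect_identical(b$state, "PDR")
  expect_equal(b$age, b0$age + 1)
  expect_equal(b$dm_duration, b0$dm_duration + 1)
  expect_identical(b$bmi, b0$bmi)    # only age and duration evolve

  expect_error(annual_event(as_dr_cohort(transform(b0, state = "DEATH")),
                            frozen_hazard(0.5), rates_of(), no_death),
               "dead agent")
})

test_that("mortality uses the incremented age (event order)", {
  # qx is 1 exactly at age 60 and 0 elsewhere: an agent aged 59 at the start
  # of the year must die, proving the death draw follows the age increment
  qx <- rep(0, 201); qx[61] <- 1; qx[201] <- 1
  trap <- life_table(qx, force_terminal = FALSE)
  set.seed(2)
  a <- annual_event(one_agent_cohort("NPDR", age = 59, dm_duration = 30),
                    frozen_hazard(0.5), rates_of(), trap)
  expect_identical(a$state, "DEATH")
})

test_that("at most one forward transition per year; PRP only for agents
           that began the year in PDR", {
  set.seed(3)
  # NPDR agent with certain advancement and certain PRP: ends the year PDR
  # (no same-year bounce back)
  a <- annual_event(one_agent_cohort("NPDR"), frozen_hazard(1 - 1e-15),
                    rates_of(prp_annual = 1, vl_annual = 0), no_death)
  expect_identical(a$state, "PDR")
  # PDR agent with certain PRP reverts to NPDR
  b <- annual_event(one_agent_cohort("PDR"), frozen_hazard(0.5),
                    rates_of(prp_annual = 1, vl_annual = 0), no_death)
  expect_identical(b$state, "NPDR")
  # but a PDR agent that reaches VL is not pulled back
  c <- annual_event(one_agent_cohort("PDR"), frozen_hazard(0.5),
                    rates_of(prp_annual = 1, vl_annual = 1), no_death)
  expect_identical(c$state, "VL")
})

test_that("realized onset frequency matches the configured 7.7%", {
  cfg <- constant_config(n = 50000L, seed = 4L)
  cohort <- generate_cohort(cfg, mode = "steady_state")
  cohort$state <- "NO_DR"
  set.seed(4)
  out <- annual_event(cohort, frozen_hazard(0.5), cfg$rates, no_death)
  frac <- mean(out$state == "NPDR")
  expect_lt(abs(frac - 0.077), 3 * sqrt(0.077 * 0.923 / 50000))
})

test_that("add_entrants stamps entry year and hits the 0.715 split", {
  cfg <- default_config(n = 10L, seed = 6L)
  cohort <- generate_cohort(cfg)
  expect_identical(add_entrants(cohort, 0L, cfg, 3L), cohort)
  set.seed(6)
  grown <- add_entrants(cohort, 5000L, cfg, year = 3L)
  new <- grown[grown$entry_year == 3L, ]
  expect_identical(nrow(new), 5000L)
  expect_identical(anyDuplicated(grown$id), 0L)
  expect_lt(abs(mean(new$state == "NO_DR") - 0.715),
            3 * sqrt(0.715 * 0.285 / 5000))
})

test_that("zero-year and transition-free runs are identities", {
  cfg <- default_config(n = 60L, seed = 7L)
  res0 <- run_simulation(cfg, years = 0L)
  expect_identical(as.data.frame(res0$final_cohort),
                   as.data.frame(generate_cohort(cfg)))
  expect_identical(nrow(res0$yearly_counts), 1L)

  frozen <- constant_config(n = 60L, seed = 7L,
                            rates = list(onset_annual = 0, vl_annual = 0))
  frozen$hazard <- frozen_hazard(1e-12)
  start <- generate_cohort(frozen)
  res <- run_simulation(frozen, years = 10L, table = no_death)
  expect_identical(res$final_cohort$state, start$state)
  expect_equal(res$final_cohort$age, start$age + 10)
  expect_equal(res$final_cohort$dm_duration, start$dm_duration + 10)
})

test_that("yearly counts conserve agents and absorb death monotonically", {
  cfg <- default_config(n = 300L, seed = 8L, record_history = TRUE)
  res <- run_simulation(cfg, years = 8L, entrants_per_year = 25L)
  counts <- res$yearly_counts
  entered <- 300L + 25L * counts$year
  expect_equal(rowSums(counts[, DR_STATES]), entered)
  expect_true(all(diff(counts$DEATH) >= 0))
  # agents ever reaching VL never un-reach it (from history records)
  h <- res$history
  ever_vl <- vapply(0:8, function(y)
    length(unique(h$id[h$state == "VL" & h$year <= y])), integer(1))
  expect_true(all(diff(ever_vl) >= 0))
})

test_that("with no PRP each agent's living-state index is non-decreasing", {
  cfg <- default_config(n = 400L, seed = 9L, record_history = TRUE)
  res <- run_simulation(cfg, years = 10L)
  h <- res$history
  h <- h[order(h$id, h$year), ]
  idx <- dr_state_index(h$state)
  same_agent <- diff(h$id) == 0
  expect_true(all(diff(idx)[same_agent] > 0))
  # histories start at the entry year and are non-decreasing in year
  expect_true(all(diff(h$year)[same_agent] > 0))
  first <- h[!duplicated(h$id), ]
  expect_equal(first$year, res$final_cohort$entry_year[
    match(first$id, res$final_cohort$id)])
})

test_that("engine matches the analytic Markov chain for frozen agents", {
  p <- 0.21; q <- 0.02
  rates <- rates_of(onset_annual = 0.077, vl_annual = 0.007,
                    prp_annual = 0.1)
  cfg <- constant_config(n = 50000L, seed = 10L, rates = rates)
  cfg$hazard <- frozen_hazard(p)
  res <- run_simulation(cfg, years = 10L, mode = "steady_state",
                        table = flat_table(q))
  observed <- unlist(res$yearly_counts[11L, DR_STATES]) / 50000

  # independent oracle: 10-step distribution by transition-matrix powers,
  # from the exact initial assignment law of steady-state mode
  M <- transition_matrix(p, q, rates)
  start <- c(0.715, 0.285 * (1 - p), 0.285 * p, 0, 0)
  expected <- start
  for (i in 1:10) expected <- expected %*% M
  expected <- drop(expected)
  se <- sqrt(expected * (1 - expected) / 50000)
  expect_true(all(abs(observed - expected) <= 3 * se + 1e-12))
})

test_that("transition_matrix rows are stochastic and respect the graph", {
  M <- transition_matrix(p = 0.3, q = 0.05, rates_of(prp_annual = 0.2))
  expect_equal(unname(rowSums(M)), rep(1, 5))
  expect_equal(M["DEATH", "DEATH"], 1)          # absorbing
  expect_equal(M["VL", c("NO_DR", "NPDR", "PDR")], c(NO_DR = 0, NPDR = 0,
                                                     PDR = 0))
  expect_equal(M["NPDR", "NO_DR"], 0)           # no backward edge to NO_DR
})

test_that("summarize_groups handles empty and toy groups", {
  cfg <- default_config(n = 30L, seed = 11L)
  allalive <- run_simulation(cfg, years = 3L, table = zero_mortality_table())
  expect_identical(allalive$deceased_summary$n, 0L)
  expect_true(is.na(allalive$deceased_summary$mean_age))

  reset_agent_ids()
  two <- rbind(as.data.frame(make_agent(fixture_profile(age = 60), "NPDR")),
               as.data.frame(make_agent(fixture_profile(age = 80), "NPDR")))
  two$state[2] <- "DEATH"
  g <- summarize_groups(as_dr_cohort(two))
  expect_equal(g$survivors$mean_age, 60)
  expect_equal(g$deceased$mean_age, 80)
  expect_identical(g$deceased$state_counts[["DEATH"]], 1L)
})

test_that("simulation results serialize to JSON", {
  res <- run_simulation(default_config(n = 50L, seed = 12L), years = 2L)
  path <- withr::local_tempfile(fileext = ".json")
  simulation_to_json(res, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$yearly_counts$year, 0:2)
  expect_equal(back$seed, 12L)
  expect_equal(back$config$rates$onset_annual, 0.077)
})
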