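#' @keywords internal
"_PACKAGE"

## Five-state statechart for diabetic retinopathy.
## States are numbered 1-5; DEATH is absorbing, VL absorbing except to DEATH,
## and the only backward edge among living states is PDR -> NPDR (pan-retinal
## photocoagulation).

#' Diabetic retinopathy statechart states
#'
#' The disease model has exactly five states, in severity order:
#' `NO_DR` (1, no retinopathy), `NPDR` (2, non-proliferative DR),
#' `PDR` (3, proliferative DR), `VL` (4, legal vision loss) and
#' `DEATH` (5). `DEATH` is absorbing; `VL` can only transition to `DEATH`;
#' the single backward edge among living states is `PDR -> NPDR`,
#' representing pan-retinal photocoagulation (PRP).
#'
#' @format A character vector of the five state names, in index order.
#' @export
DR_STATES <- c("NO_DR", "NPDR", "PDR", "VL", "DEATH")

## Permitted directed edges of the statechart (from -> to).
.DR_EDGES <- rbind(
  c("NO_DR", "NPDR"),
  c("NPDR",  "PDR"),
  c("PDR",   "VL"),
  c("PDR",   "NPDR"),   # PRP back-transition
  c("NO_DR", "DEATH"),
  c("NPDR",  "DEATH"),
  c("PDR",   "DEATH"),
  c("VL",    "DEATH")
)

#' State index in the 1-5 statechart numbering
#'
#' @param state character vector of state names.
#' @return Integer vector of indices (1 = `NO_DR` ... 5 = `DEATH`).
#' @export
dr_state_index <- function(state) {
  idx <- match(state, DR_STATES)
  if (anyNA(idx)) {
    stop("unknown DR state: ", paste(unique(state[is.na(idx)]), collapse = ", "))
  }
  idx
}

#' Check that a state transition is a permitted statechart edge
#'
#' Self-loops (remaining in a state) are always allowed; any other pair must
#' be one of the directed edges of the statechart.
#'
#' @param from,to state names (vectors recycle).
#' @return Invisibly `TRUE`; raises an error on a forbidden edge.
#' @export
check_transition <- function(from, to) {
  dr_state_index(from)
  dr_state_index(to)
  moved <- from != to
  if (any(moved)) {
    key <- paste(from[moved], to[moved], sep = "->")
    ok <- key %in% paste(.DR_EDGES[, 1], .DR_EDGES[, 2], sep = "->")
    if (!all(ok)) {
      stop("forbidden statechart transition(s): ",
           paste(unique(key[!ok]), collapse = ", "))
    }
  }
  invisible(TRUE)
}

## Column layout shared by profiles, agents and the cohort CSV.
.PROFILE_FIELDS <- c("age", "male", "dm_duration", "bmi", "hba1c",
                     "hypertension", "dyslipidemia", "nephropathy", "tobacco")
.FLAG_FIELDS <- c("male", "hypertension", "dyslipidemia", "nephropathy",
                  "tobacco")
.COHORT_COLUMNS <- c("id", .PROFILE_FIELDS, "state", "entry_year")

#' Construct a predictor profile
#'
#' A profile carries the agent-level predictors abstracted from chart data:
#' age (years), gender, diabetes duration (years), BMI (kg/m2), most recent
#' HbA1c (%), and four dichotomous comorbidity flags.
#'
#' @param age age in years (>= 18).
#' @param male logical.
#' @param dm_duration diabetes duration in years (>= 0 and <= age - 18:
#'   onset of diabetes is constrained to adulthood so resampling cannot
#'   produce children with decades of disease).
#' @param bmi body-mass index, kg/m2 (> 0).
#' @param hba1c glycated hemoglobin, percent (> 0).
#' @param hypertension,dyslipidemia,nephropathy,tobacco logical comorbidity /
#'   exposure flags.
#' @return A one-row `data.frame` with the nine predictor columns.
#' @export
predictor_profile <- function(age, male, dm_duration, bmi, hba1c,
                              hypertension = FALSE, dyslipidemia = FALSE,
                              nephropathy = FALSE, tobacco = FALSE) {
  prof <- data.frame(age = age, male = as.logical(male),
                     dm_duration = dm_duration, bmi = bmi, hba1c = hba1c,
                     hypertension = as.logical(hypertension),
                     dyslipidemia = as.logical(dyslipidemia),
                     nephropathy = as.logical(nephropathy),
                     tobacco = as.logical(tobacco))
  validate_profile(prof)
  prof
}

#' Validate predictor-profile invariants
#'
#' @param profile a data.frame with the nine predictor columns (any number
#'   of rows).
#' @return Invisibly `TRUE`; raises an error naming the offending field.
#' @export
validate_profile <- function(profile) {
  missing <- setdiff(.PROFILE_FIELDS, names(profile))
  if (length(missing)) {
    stop("profile is missing field(s): ", paste(missing, collapse = ", "))
  }
  fail <- function(field, why) stop("invalid profile field '", field, "': ", why)
  if (any(!is.finite(profile$age)) || any(profile$age < 18)) {
    fail("age", "must be finite and >= 18")
  }
  if (any(!is.finite(profile$dm_duration)) || any(profile$dm_duration < 0)) {
    fail("dm_duration", "must be finite and >= 0")
  }
  if (any(profile$dm_duration > profile$age - 18)) {
    fail("dm_duration", "must satisfy dm_duration <= age - 18")
  }
  if (any(!is.finite(profile$bmi)) || any(profile$bmi <= 0)) {
    fail("bmi", "must be finite and > 0")
  }
  if (any(!is.finite(profile$hba1c)) || any(profile$hba1c <= 0)) {
    fail("hba1c", "must be finite and > 0")
  }
  for (f in .FLAG_FIELDS) {
    if (anyNA(profile[[f]]) || !is.logical(profile[[f]])) {
      fail(f, "must be logical TRUE/FALSE")
    }
  }
  invisible(TRUE)
}

## Package-local counter for fresh agent ids.
.drsim_env <- new.env(parent = emptyenv())
.drsim_env$next_id <- 1L

.fresh_ids <- function(n) {
  ids <- seq.int(.drsim_env$next_id, length.out = n)
  .drsim_env$next_id <- .drsim_env$next_id + n
  as.integer(ids)
}

#' Reset the fresh-agent-id counter
#'
#' @param start first id handed out next (default 1).
#' @return Invisibly the previous counter value.
#' @export
reset_agent_ids <- function(start = 1L) {
  old <- .drsim_env$next_id
  .drsim_env$next_id <- as.integer(start)
  invisible(old)
}

#' Create a single agent
#'
#' An agent is one simulated patient: a predictor profile plus the current
#' statechart state and the simulation year of entry. Agents cannot be
#' created dead.
#'
#' @param profile a one-row predictor profile (see [predictor_profile()]).
#' @param state initial state name; one of [DR_STATES] except `DEATH`.
#' @param entry_year integer simulation year of cohort entry.
#' @return A one-row cohort `data.frame` (class `dr_cohort`) with a fresh
#'   unique id; its `history` attribute holds the single entry record.
#' @export
make_agent <- function(profile, state, entry_year = 0L) {
  if (!is.data.frame(profile) || nrow(profile) != 1L) {
    stop("profile must be a one-row data.frame")
  }
  validate_profile(profile)
  dr_state_index(state)
  if (state == "DEATH") stop("cannot create an agent in state DEATH")
  cohort <- cbind(data.frame(id = .fresh_ids(1L)),
                  profile[, .PROFILE_FIELDS, drop = FALSE],
                  data.frame(state = state, entry_year = as.integer(entry_year)))
  as_dr_cohort(cohort,
               history = data.frame(id = cohort$id,
                                    year = as.integer(entry_year),
                                    state = state))
}

#' Assemble a cohort data frame
#'
#' @param x a data.frame with columns `id`, the nine predictor fields,
#'   `state` and `entry_year`.
#' @param history optional long data.frame (`id`, `year`, `state`) of entry
#'   and state-change records.
#' @return `x` with class `dr_cohort` prepended.
#' @export
as_dr_cohort <- function(x, history = NULL) {
  missing <- setdiff(.COHORT_COLUMNS, names(x))
  if (length(missing)) {
    stop("cohort is missing column(s): ", paste(missing, collapse = ", "))
  }
  x <- x[, .COHORT_COLUMNS, drop = FALSE]
  rownames(x) <- NULL
  if (anyDuplicated(x$id)) stop("cohort ids must be unique")
  dr_state_index(x$state)
  if (nrow(x)) validate_profile(x)
  class(x) <- c("dr_cohort", "data.frame")
  attr(x, "history") <- history
  x
}

#' @export
print.dr_cohort <- function(x, ...) {
  cat(sprintf("<dr_cohort> %d agents (%d alive)\n",
              nrow(x), sum(x$state != "DEATH")))
  tab <- state_counts(x)
  cat(paste(sprintf("%s=%d", names(tab), tab), collapse = "  "), "\n")
  NextMethod()
}

#' Tally agents by statechart state
#'
#' @param cohort a `dr_cohort`.
#' @return Named integer vector over the five states, in index order.
#' @export
state_counts <- function(cohort) {
  tab <- table(factor(cohort$state, levels = DR_STATES))
  stats::setNames(as.integer(tab), DR_STATES)
}

#' Write a cohort to CSV
#'
#' One row per agent; logical flags serialized as 0/1, state as its name.
#'
#' @param cohort a `dr_cohort`.
#' @param path output file path.
#' @return Invisibly `path`.
#' @export
write_cohort <- function(cohort, path) {
  out <- as.data.frame(cohort)
  for (f in .FLAG_FIELDS) out[[f]] <- as.integer(out[[f]])
  out <- out[, .COHORT_COLUMNS]
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a cohort CSV written by [write_cohort()]
#'
#' @param path file path.
#' @return A `dr_cohort`.
#' @export
read_cohort <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (f in .FLAG_FIELDS) x[[f]] <- as.logical(x[[f]])
  x$id <- as.integer(x$id)
  x$entry_year <- as.integer(x$entry_year)
  as_dr_cohort(x)
}

#' Extract the history records of a cohort or simulation
#'
#' @param x a `dr_cohort` or `dr_simulation`.
#' @return A data.frame with columns `id`, `year`, `state` (entry plus each
#'   state change), or `NULL` when history recording was disabled.
#' @export
agent_history <- function(x) {
  if (inherits(x, "dr_simulation")) return(x$history)
  attr(x, "history")
}
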