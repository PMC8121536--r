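# Semi-adaptive bisection staircase.
#
# Each (delay, run) cell tracks a bracket on the indifference level:
#   kl = highest level the agent is known to have rejected (waited at); 0 if none
#   kh = lowest level the agent is known to have accepted immediately; L+1 if none
# The candidate indifference levels are {kl+1, ..., kh}. A cell is converged
# when the candidates map to a single immediate value: either kh - kl <= 1, or
# only the top level and "never accepts" remain (both worth the full reward).

.cell_converged <- function(kl, kh, L) {
  (kh - kl) <= 1L || (kh == L + 1L && kl >= L - 1L)
}

# Midpoint of the current uncertainty interval, bumped off endpoints that have
# already been tested so every trial strictly narrows the bracket.
.cell_midpoint <- function(kl, kh, L) {
  lo <- max(kl, 1L)
  hi <- min(kh, L)
  m <- (lo + hi) %/% 2L
  if (m == kl) m <- m + 1L
  if (m == kh) m <- m - 1L
  m
}

.restore_rng <- function(state) {
  if (!is.null(state$rng)) assign(".Random.seed", state$rng, envir = globalenv())
  invisible(state)
}

.capture_rng <- function(state) {
  state$rng <- get(".Random.seed", envir = globalenv())
  state
}

#' Initialize a staircase session
#'
#' Creates one uncertainty interval per (delay, run), each spanning the full
#' level range, plus a private RNG stream so that trial scheduling is
#' reproducible given `seed` and independent of the global RNG.
#'
#' @param config a [task_config()] object.
#' @param seed integer seed for the session's RNG stream.
#' @return An object of class `dd_session`.
#' @export
init_session <- function(config, seed) {
  if (!inherits(config, "dd_task")) stop("`config` must be a dd_task", call. = FALSE)
  L <- length(config$immediate_values)
  cells <- expand.grid(delay_index = seq_along(config$delays),
                       run_index = seq_len(config$n_runs))
  cells$kl <- 0L
  cells$kh <- L + 1L
  cells$n_trials <- 0L
  cells$converged <- FALSE
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  rng <- get(".Random.seed", envir = globalenv())
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  structure(
    list(config = config, cells = cells, trials = list(), seed = as.integer(seed),
         rng = rng, n_trials = 0L),
    class = "dd_session")
}

#' Current uncertainty intervals of a session
#'
#' @param state a `dd_session`.
#' @return Data frame with one row per (delay, run): `delay_index`,
#'   `run_index`, `lo`, `hi` (level indices), `converged`.
#' @export
uncertainty_intervals <- function(state) {
  L <- length(state$config$immediate_values)
  data.frame(delay_index = state$cells$delay_index,
             run_index = state$cells$run_index,
             lo = pmax(state$cells$kl, 1L),
             hi = pmin(state$cells$kh, L),
             converged = state$cells$converged)
}

#' Select the next staircase trial
#'
#' Draws a (delay, run) cell uniformly among those that have not yet converged.
#' The presented level is the midpoint of that cell's uncertainty interval,
#' except on the cell's first trial, where it is drawn from the task's start
#' pool. Raises a condition of class `dd_session_complete` when every cell has
#' converged.
#'
#' @param state a `dd_session`.
#' @return A list with the trial (`delay_index`, `run_index`, `delay`,
#'   `level_index`, `immediate_value`, `trial_index`) and the updated session
#'   (RNG stream advanced) in `$state`.
#' @export
select_next_trial <- function(state) {
  open <- which(!state$cells$converged)
  if (length(open) == 0L) {
    stop(structure(class = c("dd_session_complete", "error", "condition"),
                   list(message = "all uncertainty intervals have converged",
                        call = NULL)))
  }
  L <- length(state$config$immediate_values)
  .restore_rng(state)
  i <- if (length(open) == 1L) open else sample(open, 1L)
  cell <- state$cells[i, ]
  level <- if (cell$n_trials == 0L) {
    pool <- state$config$start_pool
    if (length(pool) == 1L) pool else sample(pool, 1L)
  } else {
    .cell_midpoint(cell$kl, cell$kh, L)
  }
  state <- .capture_rng(state)
  trial <- list(cell_index = i,
                trial_index = state$n_trials + 1L,
                delay_index = cell$delay_index,
                run_index = cell$run_index,
                delay = state$config$delays[cell$delay_index],
                level_index = as.integer(level),
                immediate_value = state$config$immediate_values[level])
  trial$state <- state
  trial
}

#' Record a choice and halve the uncertainty interval
#'
#' A `"delayed"` (wait) choice at the presented level raises the lower edge of
#' the bracket (the indifference level lies above a level the agent was willing
#' to forgo); an `"immediate"` choice lowers the upper edge (the agent accepts
#' at that level, so the lowest accepted level is at or below it). The cell is
#' flagged converged as soon as the remaining candidates share one immediate
#' value.
#'
#' @param state a `dd_session`.
#' @param trial a trial produced by [select_next_trial()] on this state.
#' @param choice `"immediate"` or `"delayed"`.
#' @return The updated `dd_session`.
#' @export
record_choice <- function(state, trial, choice) {
  choice <- match.arg(choice, c("immediate", "delayed"))
  i <- trial$cell_index
  if (state$cells$converged[i]) {
    stop("cannot record a choice against a converged interval", call. = FALSE)
  }
  L <- length(state$config$immediate_values)
  m <- trial$level_index
  if (choice == "immediate") {
    state$cells$kh[i] <- min(state$cells$kh[i], m)
  } else {
    state$cells$kl[i] <- max(state$cells$kl[i], m)
  }
  state$cells$n_trials[i] <- state$cells$n_trials[i] + 1L
  state$cells$converged[i] <- .cell_converged(state$cells$kl[i], state$cells$kh[i], L)
  state$n_trials <- state$n_trials + 1L
  state$trials[[length(state$trials) + 1L]] <-
    data.frame(trial_index = state$n_trials,
               delay_index = trial$delay_index,
               delay = trial$delay,
               run_index = trial$run_index,
               level_index = trial$level_index,
               immediate_value = trial$immediate_value,
               choice = choice)
  state
}

#' Trial log of a session
#'
#' @param state a `dd_session`.
#' @return Data frame of recorded trials in presentation order.
#' @export
session_trials <- function(state) {
  if (length(state$trials) == 0L) {
    return(data.frame(trial_index = integer(), delay_index = integer(),
                      delay = numeric(), run_index = integer(),
                      level_index = integer(), immediate_value = numeric(),
                      choice = character()))
  }
  do.call(rbind, state$trials)
}

#' Extract indifference points from a converged session
#'
#' The indifference point of a (delay, run) cell is the lowest level at which
#' the agent accepts the immediate option. Cells in which the agent never chose
#' the immediate option map to the top level with `at_boundary =
#' "always_delayed"`; cells in which it never waited map to the bottom level
#' with `at_boundary = "always_immediate"`.
#'
#' @param state a `dd_session` with all intervals converged.
#' @param config optional task config (defaults to the session's own).
#' @return Data frame: `delay`, `delay_units`, `run_index`, `level_index`,
#'   `value` (immediate-scale magnitude), `sv_norm` (normalized subjective
#'   value), `at_boundary`, `n_trials`.
#' @export
extract_indifference_points <- function(state, config = state$config) {
  if (!all(state$cells$converged)) {
    stop("incomplete session: some uncertainty intervals have not converged",
         call. = FALSE)
  }
  L <- length(config$immediate_values)
  kl <- state$cells$kl
  kh <- state$cells$kh
  level <- pmin(kh, L)
  boundary <- rep("none", nrow(state$cells))
  boundary[kh == L + 1L] <- "always_delayed"
  boundary[kh == 1L & kl == 0L] <- "always_immediate"
  vn <- task_levels_norm(config)
  out <- data.frame(delay = config$delays[state$cells$delay_index],
                    delay_units = config$delay_units,
                    run_index = state$cells$run_index,
                    level_index = as.integer(level),
                    value = config$immediate_values[level],
                    sv_norm = vn[level],
                    at_boundary = boundary,
                    n_trials = state$cells$n_trials)
  out[order(out$delay, out$run_index), , drop = FALSE]
}

#' Duration of the "Processing Data" screen
#'
#' Five seconds plus the delays of every delayed option that was *not* chosen
#' (i.e. not experienced) during the previous five trials, so that choosing the
#' immediate option never shortens the experiment.
#'
#' @param window data frame of exactly 5 trials with columns `delay` and
#'   `choice`.
#' @return Duration in seconds.
#' @export
processing_screen_duration <- function(window) {
  if (!is.data.frame(window) || nrow(window) != 5L) {
    stop("`window` must contain exactly 5 trials", call. = FALSE)
  }
  5 + sum(window$delay[window$choice == "immediate"])
}

#' Run a full staircase session against a simulated agent
#'
#' Loops [select_next_trial()] / [simulate_choice()] / [record_choice()] until
#' every (delay, run) interval has converged.
#'
#' @param config a [task_config()].
#' @param agent an [agent_params()] object.
#' @param seed integer seed (drives both trial scheduling and any choice noise).
#' @return A list with `trials` (the full log) and `points` (indifference
#'   points, see [extract_indifference_points()]).
#' @export
run_session <- function(config, agent, seed) {
  state <- init_session(config, seed)
  sv_min <- task_sv_min(config)
  max_trials <- length(config$immediate_values) * nrow(state$cells) + 10L
  repeat {
    trial <- tryCatch(select_next_trial(state),
                      dd_session_complete = function(e) NULL)
    if (is.null(trial)) break
    state <- trial$state
    .restore_rng(state)
    choice <- simulate_choice(agent,
                              immediate_value = trial$immediate_value,
                              delayed_value = config$delayed_value,
                              delay = trial$delay,
                              sv_min = sv_min,
                              level = trial$level_index)
    state <- .capture_rng(state)
    if (!is.character(choice) || !choice %in% c("immediate", "delayed")) {
      stop("agent policy returned an invalid choice token", call. = FALSE)
    }
    state <- record_choice(state, trial, choice)
    if (state$n_trials > max_trials) stop("staircase failed to terminate", call. = FALSE)
  }
  list(trials = session_trials(state),
       points = extract_indifference_points(state))
}

#' Exhaustive trial census of the staircase over threshold agents
#'
#' Runs one staircase cell through the real engine for every deterministic
#' threshold level (including the always-waits agent, encoded as `L + 1`) and
#' every start level in the task's pool, recording the number of choice trials
#' to convergence and the extracted indifference level. Because every (delay,
#' run) cell of a session is an independent copy of the same bisection, session
#' totals follow directly: a session of `C` cells totals between `C` times the
#' smallest and `C` times the largest per-cell count realizable for an agent.
#'
#' @param config a [task_config()] (default: the experiential task).
#' @return Data frame: `threshold_level`, `start_level`, `n_trials`,
#'   `level_index`, `value`, `at_boundary`.
#' @export
staircase_trial_census <- function(config = experiential_task()) {
  L <- length(config$immediate_values)
  out <- list()
  for (thr in seq_len(L + 1L)) {
    for (s in config$start_pool) {
      cfg1 <- task_config(config$task_kind, config$immediate_values,
                          config$delayed_value, delays = config$delays[1],
                          delay_units = config$delay_units, n_runs = 1L,
                          start_pool = s)
      res <- run_session(cfg1, agent_params("threshold", threshold_level = thr),
                         seed = 1L)
      out[[length(out) + 1L]] <- data.frame(
        threshold_level = thr, start_level = s,
        n_trials = nrow(res$trials),
        level_index = res$points$level_index,
        value = res$points$value,
        at_boundary = res$points$at_boundary,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
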