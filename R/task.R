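#' Task configuration for an intertemporal choice session
#'
#' Defines the grid of immediate-reward levels, the fixed delayed reward, the
#' delay grid and the staircase bookkeeping parameters for either task flavour.
#' Levels are indexed 1..L in order of *increasing* immediate value, so the
#' highest level always equals the delayed reward on the immediate scale.
#'
#' @param task_kind `"experiential"` or `"hypothetical"`.
#' @param immediate_values strictly increasing immediate-option magnitudes
#'   (visible fraction of the photograph, or dollars).
#' @param delayed_value magnitude of the delayed reward (1.0 or 100).
#' @param delays strictly increasing positive delays.
#' @param delay_units unit label for `delays` (`"s"` or `"days"`).
#' @param n_runs number of staircase repetitions per delay.
#' @param start_pool level indices eligible as the first presentation of a
#'   (delay, run) staircase.
#' @param response_buffer_s seconds before responding is enabled (bookkeeping
#'   only; nothing sleeps).
#' @param reward_display_s seconds of reward display (bookkeeping only).
#' @return An object of class `dd_task`.
#' @seealso [experiential_task()], [hypothetical_task()]
#' @export
task_config <- function(task_kind,
                        immediate_values,
                        delayed_value,
                        delays,
                        delay_units,
                        n_runs = 2L,
                        start_pool,
                        response_buffer_s = 2,
                        reward_display_s = 5) {
  task_kind <- match.arg(task_kind, c("experiential", "hypothetical"))
  L <- length(immediate_values)
  if (L < 2 || any(diff(immediate_values) <= 0)) {
    stop("invalid task config: `immediate_values` must be strictly increasing",
         call. = FALSE)
  }
  if (!isTRUE(all.equal(max(immediate_values), delayed_value))) {
    stop("invalid task config: max(immediate_values) must equal delayed_value",
         call. = FALSE)
  }
  if (any(delays <= 0) || any(diff(delays) <= 0)) {
    stop("invalid task config: `delays` must be strictly increasing and > 0",
         call. = FALSE)
  }
  if (n_runs < 1) {
    stop("invalid task config: `n_runs` must be >= 1", call. = FALSE)
  }
  if (!all(start_pool %in% seq_len(L))) {
    stop("invalid task config: `start_pool` must be a subset of 1..", L,
         call. = FALSE)
  }
  structure(
    list(task_kind = task_kind,
         immediate_values = as.numeric(immediate_values),
         delayed_value = as.numeric(delayed_value),
         delays = as.numeric(delays),
         delay_units = delay_units,
         n_runs = as.integer(n_runs),
         start_pool = as.integer(start_pool),
         response_buffer_s = response_buffer_s,
         reward_display_s = reward_display_s),
    class = "dd_task")
}

#' Default experiential task: 10 occlusion levels, delays of 1--25 seconds
#'
#' Immediate options reveal 13, 28, 45, 60, 70, 80, 88, 95, 97 and 100 percent
#' of a photograph; the delayed option is the full photograph after 1, 2, 4, 6,
#' 8, 10, 12, 14, 16, 20 or 25 seconds. Two staircase runs per delay; the first
#' trial of each staircase starts at level 4, 5 or 6.
#' @return A `dd_task`.
#' @export
experiential_task <- function() {
  task_config("experiential",
              immediate_values = c(.13, .28, .45, .60, .70, .80, .88, .95, .97, 1.00),
              delayed_value = 1.0,
              delays = c(1, 2, 4, 6, 8, 10, 12, 14, 16, 20, 25),
              delay_units = "s",
              n_runs = 2L,
              start_pool = 4:6)
}

#' Default hypothetical task: $1--$100 now versus $100 delayed
#'
#' Immediate amounts $1, 5, 10, 20, 30, 40, 50, 60, 70, 80, 90, 95, 99, 100
#' against $100 after 1 day to 10 years (delays in days; month = 30 d,
#' year = 365 d). The start pool is the middle three of the 14 levels.
#' @return A `dd_task`.
#' @export
hypothetical_task <- function() {
  task_config("hypothetical",
              immediate_values = c(1, 5, 10, 20, 30, 40, 50, 60, 70, 80, 90, 95, 99, 100),
              delayed_value = 100,
              delays = c(1, 2, 7, 14, 30, 91, 182, 365, 730, 1825, 3650),
              delay_units = "days",
              n_runs = 2L,
              start_pool = 7:9)
}

#' Minimum subjective value of a task (immediate-scale fraction)
#'
#' The lowest immediate level expressed as a fraction of the delayed reward:
#' 0.13 for the experiential grid, 0.01 for the hypothetical grid.
#' @param task a `dd_task`.
#' @export
task_sv_min <- function(task) {
  min(task$immediate_values) / task$delayed_value
}

#' Level values of a task on the normalized subjective-value scale
#'
#' Immediate values as fractions of the delayed reward, rescaled so the lowest
#' level maps to 0 and the delayed reward to 1 (see [normalize_sv()]).
#' @param task a `dd_task`.
#' @return Numeric vector of length `length(task$immediate_values)`.
#' @export
task_levels_norm <- function(task) {
  v <- task$immediate_values / task$delayed_value
  normalize_sv(v, task_sv_min(task))
}

#' @export
print.dd_task <- function(x, ...) {
  cat(sprintf("<dd_task: %s> %d levels, %d delays (%s), %d run(s)\n",
              x$task_kind, length(x$immediate_values), length(x$delays),
              x$delay_units, x$n_runs))
  invisible(x)
}
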