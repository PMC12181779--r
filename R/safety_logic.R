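# Firmware safety state machine. Three independent guards gate the
# control loop:
#
#   pause   - the pause button suspends all corrective action for a fixed
#             countdown so the incubator can be opened without triggering
#             a burst of CO2 on the ensuing concentration drop; a second
#             press restarts the countdown.
#   freeze  - a sensor returning the identical value for longer than a
#             minute is treated as potentially faulty; action is frozen
#             until a differing reading arrives, which clears the freeze
#             automatically.
#   latch   - a room CO2 reading above the leak threshold closes the
#             valve and latches the system off; the latch never clears on
#             its own and requires an explicit reset (the software
#             equivalent of a reboot after corrective action).

#' Safety configuration
#'
#' @param pause_duration_s countdown after a pause press, seconds.
#' @param stuck_window_s duration of identical readings that triggers the
#'   stuck-sensor freeze, seconds.
#' @param env_check_period_s cadence of the environmental leak check,
#'   seconds.
#' @param env_threshold_ppm room concentration above which a leak is
#'   assumed. The default, 2000 ppm, is well above typical occupied-room
#'   levels yet far below the 5000 ppm occupational exposure limit.
#' @return An object of class `"safety_config"`.
#' @export
safety_config <- function(pause_duration_s = 60, stuck_window_s = 60,
                          env_check_period_s = 30,
                          env_threshold_ppm = 2000) {
  check_num(pause_duration_s, "pause_duration_s", lower = 1e-9)
  check_num(stuck_window_s, "stuck_window_s", lower = 1e-9)
  check_num(env_check_period_s, "env_check_period_s", lower = 1e-9)
  check_num(env_threshold_ppm, "env_threshold_ppm", lower = 1e-9)
  structure(list(pause_duration_s = pause_duration_s,
                 stuck_window_s = stuck_window_s,
                 env_check_period_s = env_check_period_s,
                 env_threshold_ppm = env_threshold_ppm),
            class = "safety_config")
}

#' Safety state
#'
#' @param pause_until_s control is suspended until this time (`-Inf` when
#'   not paused).
#' @param last_reading_ppm,last_change_s stuck-detection memory: the last
#'   distinct reading and when it first appeared.
#' @param frozen logical; stuck-sensor freeze active.
#' @param latched logical; environmental leak latch. Never clears without
#'   [safety_reset()].
#' @return An object of class `"safety_state"`.
#' @export
safety_state <- function(pause_until_s = -Inf,
                         last_reading_ppm = NA_real_,
                         last_change_s = NA_real_,
                         frozen = FALSE, latched = FALSE) {
  structure(list(pause_until_s = pause_until_s,
                 last_reading_ppm = last_reading_ppm,
                 last_change_s = last_change_s,
                 frozen = frozen, latched = latched),
            class = "safety_state")
}

#' Register a pause-button press
#'
#' Starts (or restarts, on a repeated press) the pause countdown:
#' corrective action is disallowed until `now_s + pause_duration_s`.
#'
#' @param state a [safety_state()].
#' @param now_s current time, seconds.
#' @param config a [safety_config()].
#' @return Updated `"safety_state"`.
#' @export
pause_press <- function(state, now_s, config) {
  stopifnot(inherits(state, "safety_state"),
            inherits(config, "safety_config"))
  state$pause_until_s <- now_s + config$pause_duration_s
  state
}

#' Update stuck-sensor detection with a new reading
#'
#' Called on every accepted reading. Readings are compared after integer
#' rounding (the sensor reports integer ppm). The identical value
#' persisting for more than `stuck_window_s` sets the freeze; any
#' differing reading clears it and resets the memory.
#'
#' @param state a [safety_state()].
#' @param reading_ppm the accepted reading, ppm.
#' @param now_s current time, seconds.
#' @param config a [safety_config()].
#' @return Updated `"safety_state"`.
#' @export
stuck_check <- function(state, reading_ppm, now_s, config) {
  stopifnot(inherits(state, "safety_state"),
            inherits(config, "safety_config"))
  r <- round_half_up(reading_ppm)
  if (is.na(state$last_reading_ppm) || r != state$last_reading_ppm) {
    state$last_reading_ppm <- r
    state$last_change_s <- now_s
    state$frozen <- FALSE
  } else if (now_s - state$last_change_s > config$stuck_window_s) {
    state$frozen <- TRUE
  }
  state
}

#' Environmental leak check
#'
#' Intended to be invoked at the `env_check_period_s` cadence. A room
#' reading above the leak threshold latches the system: the valve is
#' forced closed and stays closed until [safety_reset()].
#'
#' @param state a [safety_state()].
#' @param env_reading_ppm room CO2 reading, ppm.
#' @param now_s current time, seconds.
#' @param config a [safety_config()].
#' @return Updated `"safety_state"`.
#' @export
env_check <- function(state, env_reading_ppm, now_s, config) {
  stopifnot(inherits(state, "safety_state"),
            inherits(config, "safety_config"))
  if (is.finite(env_reading_ppm) &&
      env_reading_ppm > config$env_threshold_ppm)
    state$latched <- TRUE
  state
}

#' Is corrective action currently allowed?
#'
#' True iff the system is not latched, not frozen, and any pause countdown
#' has elapsed.
#'
#' @param state a [safety_state()].
#' @param now_s current time, seconds.
#' @return Logical.
#' @export
is_action_allowed <- function(state, now_s) {
  stopifnot(inherits(state, "safety_state"))
  !state$latched && !state$frozen && now_s >= state$pause_until_s
}

#' Clear the leak latch
#'
#' The explicit operator reset (reboot after corrective action); the only
#' way the latch clears.
#'
#' @param state a [safety_state()].
#' @return Updated `"safety_state"` with the latch cleared.
#' @export
safety_reset <- function(state) {
  stopifnot(inherits(state, "safety_state"))
  state$latched <- FALSE
  state
}
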