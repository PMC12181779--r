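# The three control laws compared by the simulator:
#
#   TC  - threshold (bang-bang) control: valve open iff the reading is
#         below setpoint minus hysteresis, closed otherwise.
#   TAC - timed-activation control: fixed-duration valve pulses
#         (OpenShort/OpenLong) selected by how far the reading is below
#         the setpoint, followed by a mandatory lockout so the slow sensor
#         can register the change before any further action.
#   PID - discrete proportional-integral-derivative control of a
#         proportional valve whose flow is linear in coil current between
#         an opening-onset current and a full-flow current.
#
# None of the controllers can vent: there is no exhaust valve, so all
# corrective action is one-sided (inject or wait for the leak).

#' Threshold (bang-bang) controller configuration
#'
#' @param setpoint_ppm target concentration, ppm; valid setpoints span
#'   1-6% CO2 (10,000-60,000 ppm).
#' @param hysteresis_pct allowed fluctuation as a percent of the setpoint;
#'   the trigger threshold is `setpoint - setpoint * hysteresis_pct / 100`.
#' @return An object of class `"tc_config"` with the derived
#'   `hysteresis_ppm`.
#' @export
tc_config <- function(setpoint_ppm = 50000, hysteresis_pct = 0.5) {
  check_num(setpoint_ppm, "setpoint_ppm", lower = 10000, upper = 60000)
  check_num(hysteresis_pct, "hysteresis_pct", lower = 1e-9)
  structure(list(setpoint_ppm = setpoint_ppm,
                 hysteresis_pct = hysteresis_pct,
                 hysteresis_ppm = setpoint_ppm * hysteresis_pct / 100),
            class = "tc_config")
}

#' Timed-activation controller configuration
#'
#' @inheritParams tc_config
#' @param open_short_s valve-open duration for small corrections, seconds.
#' @param open_long_s duration for large corrections, seconds.
#' @param post_response_wait_s lockout after a response completes before
#'   any further action, seconds (at least 60, matching the sensor's
#'   30-second update time with margin).
#' @param long_boundary_ppm deviation below setpoint above which the long
#'   pulse is used; defaults to 4x the hysteresis band so steady-state
#'   corrections stay on the short pulse while the initial fill-up uses
#'   the long one.
#' @return An object of class `"tac_config"`.
#' @export
tac_config <- function(setpoint_ppm = 50000, hysteresis_pct = 0.5,
                       open_short_s = 2, open_long_s = 6,
                       post_response_wait_s = 60,
                       long_boundary_ppm = NULL) {
  base <- tc_config(setpoint_ppm, hysteresis_pct)
  check_num(open_short_s, "open_short_s", lower = 1e-9)
  check_num(open_long_s, "open_long_s", lower = open_short_s)
  check_num(post_response_wait_s, "post_response_wait_s", lower = 60)
  if (is.null(long_boundary_ppm))
    long_boundary_ppm <- 4 * base$hysteresis_ppm
  check_num(long_boundary_ppm, "long_boundary_ppm",
            lower = base$hysteresis_ppm + 1e-12)
  structure(c(unclass(base),
              list(open_short_s = open_short_s,
                   open_long_s = open_long_s,
                   post_response_wait_s = post_response_wait_s,
                   long_boundary_ppm = long_boundary_ppm)),
            class = "tac_config")
}

#' Timed-activation scheduler state
#'
#' @param last_response_end_s time the last valve pulse completed, seconds
#'   (`-Inf` before any response).
#' @param valve_open_until_s scheduled close time of the current pulse.
#' @return An object of class `"tac_scheduler_state"`.
#' @export
tac_scheduler_state <- function(last_response_end_s = -Inf,
                                valve_open_until_s = -Inf) {
  structure(list(last_response_end_s = last_response_end_s,
                 valve_open_until_s = valve_open_until_s),
            class = "tac_scheduler_state")
}

#' PID controller configuration
#'
#' Discrete PID on the error `e = setpoint - measurement`:
#' `u = kp*e + ki*integral(e) + kd*de/dt`, with the integral accumulator
#' clamped to `+/- integral_limit` for anti-windup and the derivative
#' taken on the error (the previous error is initialized to the first
#' error seen, avoiding a derivative kick at startup).
#'
#' @param kp,ki,kd proportional, integral and derivative gains. Defaults
#'   are the hand-tuned values 20, 0.6 and 5.
#' @param dt_s control period in seconds.
#' @param output_to_mA scale from control signal `u` to valve coil current
#'   in mA (default 0.01 mA per unit of `u`).
#' @param integral_limit anti-windup clamp on the integral accumulator; by
#'   default the value whose `ki`-weighted contribution equals full-scale
#'   valve current.
#' @param valve a [proportional_valve_params()] used only to derive the
#'   default `integral_limit`.
#' @return An object of class `"pid_config"`.
#' @export
pid_config <- function(kp = 20, ki = 0.6, kd = 5, dt_s = 1,
                       output_to_mA = 0.01, integral_limit = NULL,
                       valve = proportional_valve_params()) {
  check_num(kp, "kp"); check_num(ki, "ki", lower = 0)
  check_num(kd, "kd", lower = 0)
  check_num(dt_s, "dt_s", lower = .Machine$double.xmin)
  check_num(output_to_mA, "output_to_mA", lower = .Machine$double.xmin)
  if (is.null(integral_limit))
    integral_limit <- if (ki > 0)
      valve$full_open_mA / (output_to_mA * ki) else Inf
  if (!(integral_limit > 0)) stop("integral_limit must be > 0",
                                  call. = FALSE)
  structure(list(kp = kp, ki = ki, kd = kd, dt_s = dt_s,
                 output_to_mA = output_to_mA,
                 integral_limit = integral_limit),
            class = "pid_config")
}

#' PID controller state
#'
#' @param integral_accum running value of the error integral.
#' @param prev_error error at the previous step; `NA` until the first step.
#' @return An object of class `"pid_state"`.
#' @export
pid_state <- function(integral_accum = 0, prev_error = NA_real_) {
  structure(list(integral_accum = integral_accum, prev_error = prev_error),
            class = "pid_state")
}

#' Proportional valve current-to-flow parameters
#'
#' The valve starts to open at `open_onset_mA` and reaches maximum flow at
#' `full_open_mA`, with flow linear in current between the two.
#'
#' @param open_onset_mA coil current at which flow begins (default 160 mA).
#' @param full_open_mA coil current at maximum flow (default 330 mA).
#' @return An object of class `"proportional_valve_params"`.
#' @export
proportional_valve_params <- function(open_onset_mA = 160,
                                      full_open_mA = 330) {
  check_num(open_onset_mA, "open_onset_mA", lower = 0)
  check_num(full_open_mA, "full_open_mA", lower = open_onset_mA + 1e-12)
  structure(list(open_onset_mA = open_onset_mA,
                 full_open_mA = full_open_mA),
            class = "proportional_valve_params")
}

#' Threshold controller decision
#'
#' Open iff the reading is strictly below `setpoint - hysteresis`; a
#' reading at or above the threshold ("surpassing" it) closes the valve,
#' so ties close. Pure function of its inputs.
#'
#' @param reading_ppm an accepted sensor reading, ppm.
#' @param config a [tc_config()].
#' @return `"open"` or `"closed"`.
#' @export
tc_decide <- function(reading_ppm, config) {
  stopifnot(inherits(config, "tc_config"))
  check_num(reading_ppm, "reading_ppm")
  if (reading_ppm < config$setpoint_ppm - config$hysteresis_ppm) "open"
  else "closed"
}

#' Timed-activation controller decision
#'
#' Within the post-response lockout, or when the reading is within the
#' hysteresis band of (or above) the setpoint, no action is taken.
#' Otherwise the deviation below setpoint selects the pulse duration:
#' the short pulse up to `long_boundary_ppm`, the long pulse beyond it.
#' A scheduled response records its close time and the start of the next
#' lockout, so responses can never overlap.
#'
#' @param reading_ppm an accepted sensor reading, ppm.
#' @param config a [tac_config()].
#' @param sched a [tac_scheduler_state()].
#' @param now_s current time, seconds.
#' @return A list with `response` (`NA` for none, else the pulse duration
#'   in seconds) and the updated `sched`.
#' @export
tac_decide <- function(reading_ppm, config, sched, now_s) {
  stopifnot(inherits(config, "tac_config"),
            inherits(sched, "tac_scheduler_state"))
  check_num(reading_ppm, "reading_ppm")
  check_num(now_s, "now_s", lower = 0)
  if (now_s < sched$last_response_end_s + config$post_response_wait_s)
    return(list(response = NA_real_, sched = sched))
  dev <- config$setpoint_ppm - reading_ppm
  if (dev <= config$hysteresis_ppm)
    return(list(response = NA_real_, sched = sched))
  dur <- if (dev > config$long_boundary_ppm) config$open_long_s
         else config$open_short_s
  sched$valve_open_until_s <- now_s + dur
  sched$last_response_end_s <- now_s + dur
  list(response = dur, sched = sched)
}

#' One discrete PID step
#'
#' @param setpoint_ppm target concentration, ppm.
#' @param reading_ppm current measurement, ppm.
#' @param state a [pid_state()].
#' @param config a [pid_config()].
#' @return A list with the control signal `u` and the updated `state`.
#' @export
pid_step <- function(setpoint_ppm, reading_ppm, state, config) {
  stopifnot(inherits(state, "pid_state"), inherits(config, "pid_config"))
  e <- setpoint_ppm - reading_ppm
  state$integral_accum <- clip(state$integral_accum + e * config$dt_s,
                               -config$integral_limit,
                               config$integral_limit)
  prev <- if (is.na(state$prev_error)) e else state$prev_error
  deriv <- (e - prev) / config$dt_s
  u <- config$kp * e + config$ki * state$integral_accum + config$kd * deriv
  state$prev_error <- e
  list(u = u, state = state)
}

#' Map a PID control signal to a valve opening fraction
#'
#' The control signal is scaled to coil current, clamped to the valve's
#' drive range, and mapped through the valve's linear current-to-flow
#' characteristic: zero flow at or below the opening-onset current, full
#' flow at the full-open current.
#'
#' @param u control signal from [pid_step()].
#' @param valve a [proportional_valve_params()].
#' @param config a [pid_config()] (supplies `output_to_mA`).
#' @return Valve opening fraction in `[0, 1]`.
#' @export
control_to_valve_fraction <- function(u, valve, config) {
  stopifnot(inherits(valve, "proportional_valve_params"),
            inherits(config, "pid_config"))
  current_mA <- clip(u * config$output_to_mA, 0, valve$full_open_mA)
  clip((current_mA - valve$open_onset_mA) /
         (valve$full_open_mA - valve$open_onset_mA), 0, 1)
}
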