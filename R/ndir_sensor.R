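# NDIR CO2 sensor model: first-order lag, calibration bias, optional
# Gaussian read noise, range clipping, a minimum spacing between accepted
# reads, and a stuck-value fault mode.
#
# The lag is parameterized by T90, the time to reach 90% of a step change;
# for a first-order system the time constant is tau = T90 / ln(10). The
# chamber sensor defaults follow the MH-Z16 datasheet figures (0-100,000
# ppm range, T90 < 30 s, reads no closer than 1020 ms apart); the
# environment sensor defaults follow the MH-Z19E (400-5000 ppm).

#' NDIR sensor parameters
#'
#' @param range_min_ppm,range_max_ppm reporting limits in ppm; readings are
#'   clipped to this interval.
#' @param t90_s time for the output to reach 90% of a step change, seconds.
#'   0 means the sensor tracks the true concentration with no lag.
#' @param bias_fraction constant multiplicative calibration error
#'   (of-reading); 0.06 models a 6%-of-reading accuracy spec. Default 0 so
#'   reference runs are exact.
#' @param noise_sd_ppm standard deviation of per-read Gaussian noise, ppm.
#' @param min_read_interval_ms minimum spacing between accepted reads,
#'   milliseconds; earlier attempts are refused.
#' @return An object of class `"ndir_sensor_params"`.
#' @export
ndir_sensor_params <- function(range_min_ppm = 0,
                               range_max_ppm = 100000,
                               t90_s = 30,
                               bias_fraction = 0,
                               noise_sd_ppm = 0,
                               min_read_interval_ms = 1020) {
  check_num(range_min_ppm, "range_min_ppm")
  check_num(range_max_ppm, "range_max_ppm")
  if (range_min_ppm >= range_max_ppm)
    stop("range_min_ppm must be < range_max_ppm", call. = FALSE)
  check_num(t90_s, "t90_s", lower = 0)
  check_num(bias_fraction, "bias_fraction", lower = -1)
  check_num(noise_sd_ppm, "noise_sd_ppm", lower = 0)
  check_num(min_read_interval_ms, "min_read_interval_ms", lower = 0)
  structure(list(range_min_ppm = range_min_ppm,
                 range_max_ppm = range_max_ppm,
                 t90_s = t90_s,
                 bias_fraction = bias_fraction,
                 noise_sd_ppm = noise_sd_ppm,
                 min_read_interval_ms = min_read_interval_ms),
            class = "ndir_sensor_params")
}

#' Environment (room) sensor parameter preset
#'
#' Defaults for the optional room-monitoring sensor used by the leak
#' safety check: 400-5000 ppm reporting range and a slower 60-s T90. Its
#' read cadence is driven by the 30-s environmental safety check rather
#' than the fast control loop.
#'
#' @inheritParams ndir_sensor_params
#' @return An object of class `"ndir_sensor_params"`.
#' @export
env_sensor_params <- function(range_min_ppm = 400, range_max_ppm = 5000,
                              t90_s = 60, bias_fraction = 0,
                              noise_sd_ppm = 0, min_read_interval_ms = 0) {
  ndir_sensor_params(range_min_ppm, range_max_ppm, t90_s, bias_fraction,
                     noise_sd_ppm, min_read_interval_ms)
}

#' NDIR sensor state
#'
#' @param lagged_ppm internal lagged concentration in ppm.
#' @param last_read_ms wall time of the last accepted read, ms (`-Inf`
#'   until the first read).
#' @param fault `"none"` or `"stuck"`; a stuck sensor repeats
#'   `stuck_value_ppm` on every read while its internal lag keeps tracking.
#' @param stuck_value_ppm frozen reported value when `fault == "stuck"`.
#' @param last_reading_ppm most recent reported value (used to freeze on
#'   fault injection).
#' @return An object of class `"sensor_state"`.
#' @export
sensor_state <- function(lagged_ppm = 450, last_read_ms = -Inf,
                         fault = "none", stuck_value_ppm = NA_real_,
                         last_reading_ppm = NA_real_) {
  check_num(lagged_ppm, "lagged_ppm")
  fault <- match.arg(fault, c("none", "stuck"))
  structure(list(lagged_ppm = lagged_ppm,
                 last_read_ms = last_read_ms,
                 fault = fault,
                 stuck_value_ppm = stuck_value_ppm,
                 last_reading_ppm = last_reading_ppm),
            class = "sensor_state")
}

#' Advance the sensor lag toward the true concentration
#'
#' First-order relaxation with time constant `tau = t90_s / ln(10)`,
#' applied as the exact exponential update, so after exactly `t90_s`
#' seconds of a held step the lagged value has covered 90% of the change.
#'
#' @param state a [sensor_state()].
#' @param true_ppm true chamber concentration, ppm.
#' @param dt elapsed time, seconds, > 0.
#' @param params a [ndir_sensor_params()].
#' @return Updated `"sensor_state"`.
#' @export
sensor_lag_step <- function(state, true_ppm, dt, params) {
  stopifnot(inherits(state, "sensor_state"),
            inherits(params, "ndir_sensor_params"))
  check_num(true_ppm, "true_ppm")
  check_num(dt, "dt", lower = .Machine$double.xmin)
  if (params$t90_s == 0) {
    state$lagged_ppm <- true_ppm
  } else {
    tau <- params$t90_s / log(10)
    state$lagged_ppm <- state$lagged_ppm +
      (true_ppm - state$lagged_ppm) * (1 - exp(-dt / tau))
  }
  state
}

#' Attempt a sensor read
#'
#' A read attempted less than `min_read_interval_ms` after the last
#' accepted read is refused: `accepted` is `FALSE`, the reading is `NA`,
#' and the state is unchanged. Refusal is an ordinary outcome the caller
#' must handle, not an error. An accepted read reports
#' `clip(lagged * (1 + bias) + noise, range)` rounded to integer ppm
#' (mimicking the serial protocol), or the frozen value if the sensor is
#' stuck. Noise, when enabled, draws from the session RNG, so seeding makes
#' read sequences reproducible.
#'
#' @param state a [sensor_state()].
#' @param now_ms current wall time in milliseconds.
#' @param params a [ndir_sensor_params()].
#' @return A list with `state` (updated), `reading` (ppm or `NA`), and
#'   `accepted` (logical).
#' @export
sensor_read <- function(state, now_ms, params) {
  stopifnot(inherits(state, "sensor_state"),
            inherits(params, "ndir_sensor_params"))
  check_num(now_ms, "now_ms", lower = 0)
  if (now_ms - state$last_read_ms < params$min_read_interval_ms)
    return(list(state = state, reading = NA_real_, accepted = FALSE))
  if (state$fault == "stuck") {
    reading <- state$stuck_value_ppm
  } else {
    x <- state$lagged_ppm * (1 + params$bias_fraction)
    if (params$noise_sd_ppm > 0)
      x <- x + stats::rnorm(1, 0, params$noise_sd_ppm)
    reading <- round_half_up(clip(x, params$range_min_ppm,
                                  params$range_max_ppm))
  }
  state$last_read_ms <- now_ms
  state$last_reading_ppm <- reading
  list(state = state, reading = reading, accepted = TRUE)
}

#' Inject or clear a sensor fault
#'
#' `"stuck"` freezes the reported value at the last reading (or the
#' current lagged value if nothing has been read yet); the internal lag
#' keeps tracking the true concentration, so clearing the fault resumes
#' normal behavior immediately.
#'
#' @param state a [sensor_state()].
#' @param fault `"none"` or `"stuck"`.
#' @param value_ppm optional explicit frozen value for `"stuck"`.
#' @return Updated `"sensor_state"`.
#' @export
inject_fault <- function(state, fault = c("none", "stuck"),
                         value_ppm = NULL) {
  stopifnot(inherits(state, "sensor_state"))
  fault <- match.arg(fault)
  state$fault <- fault
  if (fault == "stuck") {
    state$stuck_value_ppm <- if (!is.null(value_ppm)) value_ppm
      else if (!is.na(state$last_reading_ppm)) state$last_reading_ppm
      else round_half_up(state$lagged_ppm)
  } else {
    state$stuck_value_ppm <- NA_real_
  }
  state
}
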