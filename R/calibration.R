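# Setpoint calibration: the mapping from a CO2 setpoint (percent) to the
# hysteresis band and valve opening times that hold it stably in a
# 50-60 L incubator, plus volume scaling, serial-setpoint parsing, and a
# small JSON settings file standing in for the firmware's non-volatile
# memory.
#
# The calibration is anchored at three validated rows:
#
#   setpoint %   hysteresis %   OpenLong s   OpenShort s
#        1            2             4            1
#        2            1             4            1
#        5            0.5           6            2
#
# Between anchors the mapping is piecewise-linear (a convention: only the
# anchors are validated); above 5% the 5% row is used unchanged.

.calib_anchors <- data.frame(
  setpoint_pct   = c(1, 2, 5),
  hysteresis_pct = c(2, 1, 0.5),
  open_long_s    = c(4, 4, 6),
  open_short_s   = c(1, 1, 2)
)

.reference_volume_L <- 55

#' Calibration settings
#'
#' The firmware variables a setpoint change adjusts, plus the pause
#' duration. Factory defaults are the standard 5% row: hysteresis 0.5%,
#' OpenLong 6 s, OpenShort 2 s, pause 60 s.
#'
#' @param setpoint_pct CO2 setpoint in percent, within 1-6.
#' @param hysteresis_pct allowed fluctuation as percent of setpoint.
#' @param open_long_s,open_short_s valve opening times, seconds.
#' @param pause_duration_s pause-button countdown, seconds.
#' @return An object of class `"calibration_settings"`.
#' @export
calibration_settings <- function(setpoint_pct = 5, hysteresis_pct = 0.5,
                                 open_long_s = 6, open_short_s = 2,
                                 pause_duration_s = 60) {
  check_num(setpoint_pct, "setpoint_pct", lower = 1, upper = 6)
  check_num(hysteresis_pct, "hysteresis_pct", lower = 1e-9)
  check_num(open_short_s, "open_short_s", lower = 1e-9)
  check_num(open_long_s, "open_long_s", lower = open_short_s)
  check_num(pause_duration_s, "pause_duration_s", lower = 1e-9)
  structure(list(setpoint_pct = setpoint_pct,
                 hysteresis_pct = hysteresis_pct,
                 open_long_s = open_long_s,
                 open_short_s = open_short_s,
                 pause_duration_s = pause_duration_s),
            class = "calibration_settings")
}

#' Derive calibration settings for a setpoint
#'
#' Returns the anchor rows exactly at 1, 2 and 5%, piecewise-linear
#' interpolation between anchors, and the 5% row for setpoints above 5%
#' (validated up to 6%, but with no separate row).
#'
#' @param setpoint_pct CO2 setpoint in percent; must lie in `[1, 6]`.
#' @return A [calibration_settings()] object.
#' @export
#' @examples
#' calibrate_setpoint(5)    # hysteresis 0.5%, OpenLong 6 s, OpenShort 2 s
#' calibrate_setpoint(3.5)  # interpolated: 0.75%, 5 s, 1.5 s
calibrate_setpoint <- function(setpoint_pct) {
  if (!is.numeric(setpoint_pct) || length(setpoint_pct) != 1 ||
      !is.finite(setpoint_pct))
    stop("setpoint must be a single finite number", call. = FALSE)
  if (setpoint_pct < 1 || setpoint_pct > 6)
    stop(sprintf(
      "setpoint %.4g%% is outside the supported 1-6%% range", setpoint_pct),
      call. = FALSE)
  a <- .calib_anchors
  p <- min(setpoint_pct, max(a$setpoint_pct))  # clamp above the top anchor
  interp <- function(col)
    stats::approx(a$setpoint_pct, a[[col]], xout = p, rule = 2)$y
  calibration_settings(setpoint_pct = setpoint_pct,
                       hysteresis_pct = interp("hysteresis_pct"),
                       open_long_s = interp("open_long_s"),
                       open_short_s = interp("open_short_s"))
}

#' Scale opening times for a non-reference incubator volume
#'
#' The anchor opening times hold for a 50-60 L incubator (reference 55 L);
#' a larger chamber needs proportionally longer injections for the same
#' concentration change, so opening times scale by `volume_L / 55` (a
#' 110 L incubator doubles them). The hysteresis band is a property of the
#' sensor/controller, not the chamber, and is unchanged.
#'
#' @param settings a [calibration_settings()].
#' @param volume_L incubator volume in litres, > 0.
#' @return Updated `"calibration_settings"`.
#' @export
scale_for_volume <- function(settings, volume_L) {
  stopifnot(inherits(settings, "calibration_settings"))
  check_num(volume_L, "volume_L", lower = 1e-12)
  f <- volume_L / .reference_volume_L
  settings$open_long_s <- settings$open_long_s * f
  settings$open_short_s <- settings$open_short_s * f
  settings
}

#' Parse a setpoint received over the serial protocol
#'
#' The device accepts a bare decimal percent over serial (sending "2.5"
#' sets 2.5% = 25,000 ppm). Non-numeric text and values outside the
#' supported range are rejected; the caller then recomputes the
#' calibration, echoes the revised settings, and persists them.
#'
#' @param text the received string.
#' @return The parsed setpoint in percent.
#' @export
parse_serial_setpoint <- function(text) {
  if (!is.character(text) || length(text) != 1)
    stop("serial setpoint must be a single string", call. = FALSE)
  v <- suppressWarnings(as.numeric(trimws(text)))
  if (is.na(v))
    stop(sprintf("cannot parse setpoint from \"%s\"", text), call. = FALSE)
  if (v < 1 || v > 6)
    stop(sprintf(
      "setpoint %.4g%% rejected: supported range is 1-6%%", v),
      call. = FALSE)
  v
}

#' Persist settings to the state file
#'
#' Writes the settings as a small JSON document, the software stand-in
#' for the firmware's non-volatile memory, so a restart resumes with the
#' retained settings.
#'
#' @param settings a [calibration_settings()].
#' @param state_path path of the state file.
#' @return `state_path`, invisibly.
#' @export
persist_settings <- function(settings, state_path) {
  stopifnot(inherits(settings, "calibration_settings"))
  jsonlite::write_json(unclass(settings), state_path, auto_unbox = TRUE,
                       digits = NA)
  invisible(state_path)
}

#' Load settings from the state file
#'
#' A missing state file yields the factory defaults (the standard 5% row).
#' A corrupt or incomplete file also falls back to the defaults, with a
#' warning, so a damaged state can never brick the controller.
#'
#' @param state_path path of the state file.
#' @return A [calibration_settings()] object.
#' @export
load_settings <- function(state_path) {
  if (!file.exists(state_path)) return(calibration_settings())
  parsed <- tryCatch(jsonlite::read_json(state_path, simplifyVector = TRUE),
                     error = function(e) NULL)
  out <- tryCatch(
    do.call(calibration_settings,
            parsed[names(parsed) %in% names(formals(calibration_settings))]),
    error = function(e) NULL)
  if (is.null(out)) {
    warning(sprintf(
      "state file '%s' is corrupt; falling back to factory defaults",
      state_path), call. = FALSE)
    out <- calibration_settings()
  }
  out
}
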