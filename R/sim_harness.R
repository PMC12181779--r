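# Closed-loop scenario runner: wires the plant, sensor, controller and
# safety state machine together on a fixed control tick (1 s by default),
# with finer plant sub-steps while the valve is open so 1-6 s pulses are
# resolved. Also: stability metrics, the three-way strategy comparison,
# and trace/scenario file I/O.

#' Define a closed-loop scenario
#'
#' Bundles everything a simulation run needs. When `control` is `NULL`
#' the controller settings for `"tc"`/`"tac"` are derived from the
#' setpoint through [calibrate_setpoint()] (so a 5% scenario gets the
#' standard 0.5% hysteresis and 6 s / 2 s opening times); `"pid"` gets
#' [pid_config()] with the hand-tuned gains 20 / 0.6 / 5.
#'
#' @param setpoint_ppm target CO2 concentration, ppm (1% = 10,000 ppm).
#' @param plant a [gas_plant_params()].
#' @param sensor the chamber sensor, a [ndir_sensor_params()].
#' @param env_sensor optional room sensor for the leak check, a
#'   [ndir_sensor_params()] (e.g. [env_sensor_params()]), or `NULL`.
#' @param controller `"tac"`, `"tc"`, `"pid"`, or `"none"` (valve stays
#'   shut; useful for baseline runs).
#' @param control controller configuration matching `controller`, or
#'   `NULL` to derive it as described above.
#' @param valve a [proportional_valve_params()] (used by PID only).
#' @param safety a [safety_config()].
#' @param duration_s run length in seconds.
#' @param tick_s control tick, seconds.
#' @param substep_s plant/sensor integration sub-step used while the valve
#'   is open, seconds.
#' @param initial_co2_ppm chamber concentration at t = 0; the default
#'   450 ppm is the ambient off-state a run starts from.
#' @param seed RNG seed applied at the start of the run; with zero sensor
#'   noise runs are already deterministic, the seed makes noisy runs
#'   reproducible too.
#' @param faults named list of fault injections: `stuck_at_s` (chamber
#'   sensor freezes at that time), `leak_at_s` + `leak_ppm` (room
#'   concentration jumps, default 3000 ppm), `pause_at_s` (vector of
#'   pause-button press times).
#' @return An object of class `"co2_scenario"`.
#' @export
scenario <- function(setpoint_ppm = 50000,
                     plant = gas_plant_params(),
                     sensor = ndir_sensor_params(),
                     env_sensor = NULL,
                     controller = c("tac", "tc", "pid", "none"),
                     control = NULL,
                     valve = proportional_valve_params(),
                     safety = safety_config(),
                     duration_s = 7200,
                     tick_s = 1,
                     substep_s = 0.1,
                     initial_co2_ppm = 450,
                     seed = 1L,
                     faults = list()) {
  controller <- match.arg(controller)
  stopifnot(inherits(plant, "gas_plant_params"),
            inherits(sensor, "ndir_sensor_params"),
            is.null(env_sensor) || inherits(env_sensor, "ndir_sensor_params"),
            inherits(valve, "proportional_valve_params"),
            inherits(safety, "safety_config"))
  check_num(setpoint_ppm, "setpoint_ppm", lower = 10000, upper = 60000)
  check_num(duration_s, "duration_s", lower = 1e-9)
  check_num(tick_s, "tick_s", lower = 1e-9)
  check_num(substep_s, "substep_s", lower = 1e-9, upper = tick_s)
  check_num(initial_co2_ppm, "initial_co2_ppm", lower = 0,
            upper = plant$source_ppm)
  bad <- setdiff(names(faults),
                 c("stuck_at_s", "leak_at_s", "leak_ppm", "pause_at_s"))
  if (length(bad))
    stop("unknown fault fields: ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (is.null(control)) {
    cal <- calibrate_setpoint(setpoint_ppm / 10000)
    control <- switch(controller,
      tac  = tac_config(setpoint_ppm, cal$hysteresis_pct,
                        cal$open_short_s, cal$open_long_s),
      tc   = tc_config(setpoint_ppm, cal$hysteresis_pct),
      pid  = pid_config(dt_s = tick_s, valve = valve),
      none = NULL)
  }
  hysteresis_ppm <- if (!is.null(control$hysteresis_ppm))
    control$hysteresis_ppm
  else setpoint_ppm * calibrate_setpoint(setpoint_ppm / 10000)$hysteresis_pct / 100
  structure(list(setpoint_ppm = setpoint_ppm, plant = plant,
                 sensor = sensor, env_sensor = env_sensor,
                 controller = controller, control = control,
                 valve = valve, safety = safety,
                 duration_s = duration_s, tick_s = tick_s,
                 substep_s = substep_s,
                 initial_co2_ppm = initial_co2_ppm,
                 seed = as.integer(seed), faults = faults,
                 hysteresis_ppm = hysteresis_ppm),
            class = "co2_scenario")
}

#' Reference closed-loop scenario
#'
#' The standard validation conditions: a 55 L chamber (injection
#' 0.012 L/s, leak 5e-5 /s, ambient 450 ppm), the chamber sensor with
#' T90 = 30 s and zero bias/noise, controller settings from the setpoint
#' calibration table, a 120-minute run from the 450 ppm off-state, 1-s
#' ticks with 0.1-s sub-steps during valve pulses.
#'
#' @param setpoint_pct CO2 setpoint in percent (1-6).
#' @param controller controller kind, default `"tac"`.
#' @param duration_s run length, default 7200 s.
#' @param seed RNG seed.
#' @return An object of class `"co2_scenario"`.
#' @export
reference_scenario <- function(setpoint_pct = 5, controller = "tac",
                               duration_s = 7200, seed = 1L) {
  scenario(setpoint_ppm = setpoint_pct * 10000,
           controller = controller,
           duration_s = duration_s,
           seed = seed)
}

#' Run a closed-loop simulation
#'
#' Each tick: the plant and the sensor lag are advanced (sub-stepped while
#' the valve is open), a read is attempted honoring the sensor's minimum
#' read interval (a too-early attempt is refused and simply leaves no
#' measurement on that row), stuck-sensor detection runs on every accepted
#' reading, the environmental leak check runs on its own 30-s cadence, and
#' finally -- if no safety guard is active -- the controller acts: TAC
#' schedules fixed-duration pulses, TC and PID set the valve state for the
#' next tick. Any active safety guard (pause, freeze, latch) forces the
#' valve closed and cancels a pulse in progress.
#'
#' @param sc a [scenario()].
#' @return A `"co2_trace"`: a data frame with one row per tick
#'   (`time_s`, `true_ppm`, `measured_ppm` -- `NA` on ticks whose read was
#'   refused -- `valve_fraction` averaged over the tick, and `event`),
#'   with the scenario, seed and setpoint attached as attributes.
#' @export
run_closed_loop <- function(sc) {
  stopifnot(inherits(sc, "co2_scenario"))
  set.seed(sc$seed)
  n <- as.integer(ceiling(sc$duration_s / sc$tick_s))
  tick <- sc$tick_s

  plant_st <- gas_plant_state(sc$initial_co2_ppm, 0)
  sens_st <- sensor_state(lagged_ppm = sc$initial_co2_ppm)
  env_true <- sc$plant$ambient_ppm
  env_st <- if (!is.null(sc$env_sensor))
    sensor_state(lagged_ppm = env_true) else NULL
  saf <- safety_state()
  sched <- tac_scheduler_state()
  pid_st <- pid_state()
  held_fraction <- 0      # TC/PID valve command held over the next tick
  last_reading <- NA_real_
  last_env_check <- 0
  stuck_done <- FALSE
  leak_done <- FALSE
  pauses_pending <- sort(as.numeric(sc$faults$pause_at_s %||% numeric(0)))

  time_v <- numeric(n); true_v <- numeric(n); meas_v <- rep(NA_real_, n)
  frac_v <- numeric(n); event_v <- character(n)

  for (i in seq_len(n)) {
    t0 <- (i - 1) * tick
    t1 <- i * tick
    events <- character(0)

    # scheduled fault injections take effect at the tick boundary
    if (!stuck_done && !is.null(sc$faults$stuck_at_s) &&
        t0 >= sc$faults$stuck_at_s) {
      sens_st <- inject_fault(sens_st, "stuck")
      events <- c(events, "stuck_fault_injected")
      stuck_done <- TRUE
    }
    if (!leak_done && !is.null(sc$faults$leak_at_s) &&
        t0 >= sc$faults$leak_at_s) {
      env_true <- sc$faults$leak_ppm %||% 3000
      events <- c(events, "leak_injected")
      leak_done <- TRUE
    }
    while (length(pauses_pending) && t0 >= pauses_pending[1]) {
      saf <- pause_press(saf, pauses_pending[1], sc$safety)
      events <- c(events, "pause_press")
      pauses_pending <- pauses_pending[-1]
    }

    # an active guard forces the valve closed and cancels a pulse
    if (!is_action_allowed(saf, t0)) {
      sched$valve_open_until_s <- -Inf
      held_fraction <- 0
    }

    # advance plant + sensor over [t0, t1], sub-stepping when any flow
    open_now <- if (sc$controller == "tac")
      sched$valve_open_until_s > t0 else held_fraction > 0
    dt_sub <- if (open_now) sc$substep_s else tick
    s0 <- t0
    open_time <- 0
    while (s0 < t1 - 1e-12) {
      s1 <- min(s0 + dt_sub, t1)
      u <- if (sc$controller == "tac") {
        if (s0 < sched$valve_open_until_s - 1e-12) 1 else 0
      } else held_fraction
      plant_st <- plant_step(plant_st, sc$plant, u, s1 - s0)
      sens_st <- sensor_lag_step(sens_st, plant_st$co2_ppm, s1 - s0,
                                 sc$sensor)
      open_time <- open_time + u * (s1 - s0)
      s0 <- s1
    }
    if (!is.null(env_st))
      env_st <- sensor_lag_step(env_st, env_true, tick, sc$env_sensor)

    # measurement attempt (refusals leave the row without a measurement)
    rd <- sensor_read(sens_st, t1 * 1000, sc$sensor)
    sens_st <- rd$state
    if (rd$accepted) {
      last_reading <- rd$reading
      was_frozen <- saf$frozen
      saf <- stuck_check(saf, rd$reading, t1, sc$safety)
      if (saf$frozen && !was_frozen) events <- c(events, "freeze")
      if (!saf$frozen && was_frozen) events <- c(events, "unfreeze")
    }

    # environmental leak check on its own cadence
    if (!is.null(env_st) &&
        t1 - last_env_check >= sc$safety$env_check_period_s - 1e-9) {
      last_env_check <- t1
      events <- c(events, "env_check")
      er <- sensor_read(env_st, t1 * 1000, sc$env_sensor)
      env_st <- er$state
      if (er$accepted) {
        was_latched <- saf$latched
        saf <- env_check(saf, er$reading, t1, sc$safety)
        if (saf$latched && !was_latched) {
          events <- c(events, "latch", "warning")
          sched$valve_open_until_s <- -Inf
          held_fraction <- 0
        }
      }
    }

    # controller acts only when every safety guard is clear
    if (is_action_allowed(saf, t1) && sc$controller != "none" &&
        !is.na(last_reading)) {
      if (sc$controller == "tac") {
        if (rd$accepted) {
          dec <- tac_decide(rd$reading, sc$control, sched, t1)
          sched <- dec$sched
          if (!is.na(dec$response))
            events <- c(events, sprintf("open_for_%gs", dec$response))
        }
      } else if (sc$controller == "tc") {
        cmd <- tc_decide(last_reading, sc$control)
        new_fraction <- if (cmd == "open") 1 else 0
        if (new_fraction > 0 && held_fraction == 0)
          events <- c(events, "valve_open")
        if (new_fraction == 0 && held_fraction > 0)
          events <- c(events, "valve_close")
        held_fraction <- new_fraction
      } else if (sc$controller == "pid") {
        st <- pid_step(sc$setpoint_ppm, last_reading, pid_st, sc$control)
        pid_st <- st$state
        held_fraction <- control_to_valve_fraction(st$u, sc$valve,
                                                   sc$control)
      }
    } else if (!is_action_allowed(saf, t1)) {
      sched$valve_open_until_s <- -Inf
      held_fraction <- 0
    }

    time_v[i] <- t1
    true_v[i] <- plant_st$co2_ppm
    meas_v[i] <- if (rd$accepted) rd$reading else NA_real_
    frac_v[i] <- open_time / tick
    event_v[i] <- paste(events, collapse = ";")
  }

  tr <- data.frame(time_s = time_v, true_ppm = true_v,
                   measured_ppm = meas_v, valve_fraction = frac_v,
                   event = event_v, stringsAsFactors = FALSE)
  attr(tr, "scenario") <- sc
  attr(tr, "setpoint_ppm") <- sc$setpoint_ppm
  attr(tr, "hysteresis_ppm") <- sc$hysteresis_ppm
  attr(tr, "seed") <- sc$seed
  class(tr) <- c("co2_trace", "data.frame")
  tr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Stability metrics over a trace window
#'
#' Fluctuation is characterized about the window mean of the measured
#' signal, not the setpoint: a one-sided below-threshold trigger makes
#' the loop oscillate slightly below its setpoint, and the mean-centered
#' maximal deviation is the quantity that maps cleanly onto a
#' percent-of-setpoint figure.
#'
#' @param trace a `"co2_trace"` from [run_closed_loop()] (or re-read with
#'   [read_trace()]).
#' @param window length-2 numeric, `c(t_start, t_end)` in seconds.
#' @param setpoint_ppm the setpoint the run targeted; defaults to the
#'   trace attribute when present.
#' @param hysteresis_ppm hysteresis band used for the settling-time
#'   criterion (within `+/- 2 *` band of setpoint for the rest of the
#'   run); defaults to the trace attribute.
#' @return An object of class `"stability_metrics"`: window, `mean_ppm`,
#'   `max_dev_from_mean_ppm`, `pct_of_setpoint`, `settling_time_s`,
#'   `valve_actuations` (closed-to-open transitions in the window) and
#'   `total_open_s`.
#' @export
fluctuation_metrics <- function(trace, window,
                                setpoint_ppm = attr(trace, "setpoint_ppm"),
                                hysteresis_ppm = attr(trace, "hysteresis_ppm")) {
  stopifnot(is.data.frame(trace), length(window) == 2)
  if (window[2] <= window[1]) stop("empty metrics window", call. = FALSE)
  if (is.null(setpoint_ppm))
    stop("setpoint_ppm required for a trace without attributes",
         call. = FALSE)
  inw <- trace$time_s >= window[1] & trace$time_s <= window[2]
  m <- trace$measured_ppm[inw]
  m <- m[!is.na(m)]
  if (!length(m)) stop("no accepted measurements in window", call. = FALSE)
  mu <- mean(m)
  max_dev <- max(abs(m - mu))
  # settling: measured stays within +/- 2*hysteresis of setpoint to the end
  settling <- NA_real_
  if (!is.null(hysteresis_ppm)) {
    ok_idx <- !is.na(trace$measured_ppm)
    tm <- trace$time_s[ok_idx]
    ok <- abs(trace$measured_ppm[ok_idx] - setpoint_ppm) <=
      2 * hysteresis_ppm
    good_tail <- rev(cumprod(rev(ok))) == 1
    if (any(good_tail)) settling <- tm[which(good_tail)[1]]
  }
  frac <- trace$valve_fraction[inw]
  acts <- sum(diff(c(0, frac > 0)) == 1)
  tick <- if (length(trace$time_s) > 1) diff(trace$time_s[1:2]) else 1
  structure(list(window = window, mean_ppm = mu,
                 max_dev_from_mean_ppm = max_dev,
                 pct_of_setpoint = percent_of_setpoint(max_dev,
                                                       setpoint_ppm),
                 settling_time_s = settling,
                 valve_actuations = acts,
                 total_open_s = sum(frac) * tick),
            class = "stability_metrics")
}

#' Express a deviation as a percent of the setpoint
#'
#' Fluctuations are reported as a percentage of the setpoint value, not
#' of the sensor's full measurement scale, and printed to two decimals
#' with ties rounding up (145 ppm at 20,000 ppm is 0.725% and prints as
#' 0.73).
#'
#' @param dev_ppm deviation in ppm.
#' @param setpoint_ppm setpoint in ppm, > 0.
#' @return Percent of setpoint, rounded half-up to 2 decimals.
#' @export
#' @examples
#' percent_of_setpoint(120, 10000)  # 1.2
#' percent_of_setpoint(260, 50000)  # 0.52
percent_of_setpoint <- function(dev_ppm, setpoint_ppm) {
  check_num(dev_ppm, "dev_ppm", lower = 0)
  check_num(setpoint_ppm, "setpoint_ppm", lower = 1e-9)
  round_half_up(100 * dev_ppm / setpoint_ppm, 2)
}

#' Compare the three control strategies on identical conditions
#'
#' Runs threshold (TC), timed-activation (TAC) and PID control on the
#' same plant, sensor, safety settings and seed, and summarizes each with
#' [fluctuation_metrics()] over the same window. The headline figure is
#' the TC:TAC ratio of maximal fluctuation -- how much the timed pulses
#' plus post-response lockout buy over naive bang-bang switching with a
#' slow sensor.
#'
#' @param sc a [scenario()]; its `controller`/`control` fields are
#'   ignored and each strategy gets its setpoint-calibrated settings.
#' @param window metrics window, default the final 30 minutes.
#' @return An object of class `"strategy_comparison"`: per-strategy
#'   metrics and traces, and `ratio_tc_tac`.
#' @export
compare_strategies <- function(sc, window = NULL) {
  stopifnot(inherits(sc, "co2_scenario"))
  if (is.null(window))
    window <- c(max(0, sc$duration_s - 1800), sc$duration_s)
  runs <- lapply(c(tc = "tc", tac = "tac", pid = "pid"), function(kind) {
    sck <- sc
    sck$controller <- kind
    cal <- calibrate_setpoint(sc$setpoint_ppm / 10000)
    sck$control <- switch(kind,
      tc  = tc_config(sc$setpoint_ppm, cal$hysteresis_pct),
      tac = tac_config(sc$setpoint_ppm, cal$hysteresis_pct,
                       cal$open_short_s, cal$open_long_s),
      pid = pid_config(dt_s = sc$tick_s, valve = sc$valve))
    run_closed_loop(sck)
  })
  metrics <- lapply(runs, fluctuation_metrics, window = window)
  structure(list(metrics = metrics, traces = runs, window = window,
                 setpoint_ppm = sc$setpoint_ppm,
                 ratio_tc_tac = metrics$tc$max_dev_from_mean_ppm /
                   metrics$tac$max_dev_from_mean_ppm),
            class = "strategy_comparison")
}

#' Write a trace to CSV
#'
#' @param trace a `"co2_trace"`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(is.data.frame(trace))
  utils::write.csv(trace[c("time_s", "true_ppm", "measured_ppm",
                           "valve_fraction", "event")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a trace back from CSV
#'
#' @param path CSV path written by [write_trace()].
#' @return A `"co2_trace"` data frame (run attributes are not stored in
#'   the CSV and are absent).
#' @export
read_trace <- function(path) {
  tr <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_s", "true_ppm", "measured_ppm", "valve_fraction",
            "event")
  miss <- setdiff(need, names(tr))
  if (length(miss))
    stop("trace file missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  tr$event <- as.character(tr$event)
  tr$event[is.na(tr$event)] <- ""
  class(tr) <- c("co2_trace", "data.frame")
  tr
}

#' Hash of a trace's canonical CSV rendering
#'
#' MD5 of the CSV text [write_trace()] produces; identical scenarios and
#' seeds give byte-identical traces and therefore identical hashes.
#'
#' @param trace a `"co2_trace"`.
#' @return A 32-character hex string.
#' @export
trace_hash <- function(trace) {
  f <- tempfile(fileext = ".csv")
  on.exit(unlink(f))
  write_trace(trace, f)
  unname(tools::md5sum(f))
}

# --- scenario file I/O -----------------------------------------------------

.scenario_schema <- list(
  top = c("setpoint_ppm", "plant", "sensor", "env_sensor", "controller",
          "control", "valve", "safety", "duration_s", "tick_s",
          "substep_s", "initial_co2_ppm", "seed", "faults"),
  required = c("setpoint_ppm", "plant", "sensor", "controller",
               "duration_s"),
  plant = c("volume_L", "injection_flow_Lps", "source_ppm",
            "leak_rate_per_s", "ambient_ppm"),
  sensor = c("range_min_ppm", "range_max_ppm", "t90_s", "bias_fraction",
             "noise_sd_ppm", "min_read_interval_ms"),
  valve = c("open_onset_mA", "full_open_mA"),
  safety = c("pause_duration_s", "stuck_window_s", "env_check_period_s",
             "env_threshold_ppm"),
  faults = c("stuck_at_s", "leak_at_s", "leak_ppm", "pause_at_s")
)

#' Read a scenario from a JSON or YAML configuration file
#'
#' The file is validated against the scenario schema: unknown keys are
#' rejected and missing required fields are named, with all problems
#' reported together. `plant` and `sensor` sections must be complete;
#' `valve`, `safety`, `env_sensor`, `faults` and the timing fields are
#' optional and default as in [scenario()]. YAML files (`.yml`/`.yaml`)
#' need the yaml package.
#'
#' @param path configuration file path.
#' @return An object of class `"co2_scenario"`.
#' @export
read_scenario <- function(path) {
  if (!file.exists(path)) stop("no such scenario file: ", path,
                               call. = FALSE)
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the yaml package is required for YAML scenarios",
           call. = FALSE)
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  problems <- character(0)
  sch <- .scenario_schema
  unknown <- setdiff(names(cfg), sch$top)
  if (length(unknown))
    problems <- c(problems,
                  paste0("unknown field(s): ",
                         paste(unknown, collapse = ", ")))
  missing_req <- setdiff(sch$required, names(cfg))
  if (length(missing_req))
    problems <- c(problems,
                  paste0("missing required field(s): ",
                         paste(missing_req, collapse = ", ")))
  check_section <- function(name, complete = FALSE) {
    if (is.null(cfg[[name]])) return()
    unk <- setdiff(names(cfg[[name]]), sch[[name]])
    if (length(unk))
      problems <<- c(problems, paste0(name, ": unknown field(s): ",
                                      paste(unk, collapse = ", ")))
    if (complete) {
      mis <- setdiff(sch[[name]], names(cfg[[name]]))
      if (length(mis))
        problems <<- c(problems, paste0(name, ": missing field(s): ",
                                        paste(mis, collapse = ", ")))
    }
  }
  check_section("plant", complete = TRUE)
  check_section("sensor", complete = TRUE)
  if (!is.null(cfg$env_sensor)) {
    unk <- setdiff(names(cfg$env_sensor), sch$sensor)
    if (length(unk))
      problems <- c(problems, paste0("env_sensor: unknown field(s): ",
                                     paste(unk, collapse = ", ")))
  }
  check_section("valve"); check_section("safety"); check_section("faults")
  if (length(problems))
    stop("invalid scenario configuration:\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  args <- list(
    setpoint_ppm = cfg$setpoint_ppm,
    plant = do.call(gas_plant_params, as.list(cfg$plant)),
    sensor = do.call(ndir_sensor_params, as.list(cfg$sensor)),
    controller = cfg$controller,
    duration_s = cfg$duration_s)
  if (!is.null(cfg$env_sensor))
    args$env_sensor <- do.call(ndir_sensor_params, as.list(cfg$env_sensor))
  if (!is.null(cfg$valve))
    args$valve <- do.call(proportional_valve_params, as.list(cfg$valve))
  if (!is.null(cfg$safety))
    args$safety <- do.call(safety_config, as.list(cfg$safety))
  for (f in c("tick_s", "substep_s", "initial_co2_ppm", "seed"))
    if (!is.null(cfg[[f]])) args[[f]] <- cfg[[f]]
  if (!is.null(cfg$faults)) args$faults <- as.list(cfg$faults)
  do.call(scenario, args)
}

#' Write a scenario to a JSON configuration file
#'
#' Writes the sections [read_scenario()] understands; the derived
#' controller configuration is not stored and is re-derived from the
#' setpoint on re-read.
#'
#' @param sc a [scenario()].
#' @param path output path (JSON).
#' @return `path`, invisibly.
#' @export
write_scenario <- function(sc, path) {
  stopifnot(inherits(sc, "co2_scenario"))
  out <- list(setpoint_ppm = sc$setpoint_ppm,
              plant = unclass(sc$plant),
              sensor = unclass(sc$sensor),
              controller = sc$controller,
              duration_s = sc$duration_s,
              tick_s = sc$tick_s, substep_s = sc$substep_s,
              initial_co2_ppm = sc$initial_co2_ppm, seed = sc$seed)
  if (!is.null(sc$env_sensor)) out$env_sensor <- unclass(sc$env_sensor)
  out$valve <- unclass(sc$valve)
  out$safety <- unclass(sc$safety)
  if (length(sc$faults)) out$faults <- sc$faults
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
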