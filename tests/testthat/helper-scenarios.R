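# Short scenario builders shared across test files. Durations are kept to
# a few simulated minutes; the full two-hour reference runs live in the
# stability tests only.

ref_plant <- function() gas_plant_params()

quiet_sensor <- function(...) ndir_sensor_params(...)

short_tac_scenario <- function(duration_s = 600, setpoint_pct = 5, ...) {
  scenario(setpoint_ppm = setpoint_pct * 10000, controller = "tac",
           duration_s = duration_s, ...)
}

# Independent ODE oracle for the chamber mass balance: numerical
# integration via deSolve, never the package's own exponential update.
ode_oracle <- function(c0, u, params, t_end) {
  rhs <- function(t, y, p) {
    a <- p$injection_flow_Lps * u / p$volume_L
    list(a * (p$source_ppm - y) -
           p$leak_rate_per_s * (y - p$ambient_ppm))
  }
  out <- deSolve::ode(y = c(C = c0), times = c(0, t_end), func = rhs,
                      parms = params, rtol = 1e-12, atol = 1e-8)
  unname(out[nrow(out), "C"])
}
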