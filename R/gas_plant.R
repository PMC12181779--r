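# Well-mixed chamber gas mass balance.
#
# The incubator is treated as a single well-mixed volume V receiving pure
# CO2 at volumetric flow q*u (u = valve fraction) and exchanging air with
# the room at a first-order leak rate k. In ppm units the concentration
# obeys
#
#   dC/dt = (q*u/V) * (S - C) - k * (C - A)
#
# with S the source concentration (1e6 ppm for pure gas) and A the ambient
# room concentration. For constant u over a step this linear ODE has the
# closed-form solution used by plant_step(), so the integrator is exact and
# unconditionally stable at any step size.

#' Gas plant parameters
#'
#' Physical parameters of the well-mixed incubator chamber model.
#'
#' @param volume_L chamber volume in litres. Default 55 L, mid-range of a
#'   typical 50-60 L bench incubator.
#' @param injection_flow_Lps volumetric flow of injected CO2 with the valve
#'   fully open, litres per second.
#' @param source_ppm CO2 fraction of the injected gas in ppm; pure bottled
#'   gas is 1e6.
#' @param leak_rate_per_s first-order air-exchange rate with the room, 1/s.
#' @param ambient_ppm room CO2 concentration in ppm.
#' @return An object of class `"gas_plant_params"`.
#' @export
#' @examples
#' p <- gas_plant_params()
#' plant_equilibrium(p, valve_fraction = 1)
gas_plant_params <- function(volume_L = 55,
                             injection_flow_Lps = 0.012,
                             source_ppm = 1e6,
                             leak_rate_per_s = 5e-5,
                             ambient_ppm = 450) {
  check_num(volume_L, "volume_L", lower = 1e-12)
  check_num(injection_flow_Lps, "injection_flow_Lps", lower = 0)
  check_num(source_ppm, "source_ppm", lower = 0, upper = 1e6)
  check_num(leak_rate_per_s, "leak_rate_per_s", lower = 0)
  check_num(ambient_ppm, "ambient_ppm", lower = 0, upper = source_ppm)
  structure(list(volume_L = volume_L,
                 injection_flow_Lps = injection_flow_Lps,
                 source_ppm = source_ppm,
                 leak_rate_per_s = leak_rate_per_s,
                 ambient_ppm = ambient_ppm),
            class = "gas_plant_params")
}

#' Gas plant state
#'
#' @param co2_ppm true chamber CO2 concentration in ppm.
#' @param time_s simulation clock in seconds.
#' @return An object of class `"gas_plant_state"`.
#' @export
gas_plant_state <- function(co2_ppm = 450, time_s = 0) {
  check_num(co2_ppm, "co2_ppm", lower = 0, upper = 1e6)
  check_num(time_s, "time_s")
  structure(list(co2_ppm = co2_ppm, time_s = time_s),
            class = "gas_plant_state")
}

#' Advance the chamber concentration by one step
#'
#' Integrates the chamber mass balance over `dt` seconds with the valve
#' held at `valve_fraction`, using the exact exponential solution of the
#' linear ODE: the state relaxes toward the mixing equilibrium with rate
#' `q*u/V + k_leak`. Exactness makes composition of steps associative
#' (stepping dt1 then dt2 equals stepping dt1 + dt2).
#'
#' @param state a [gas_plant_state()].
#' @param params a [gas_plant_params()].
#' @param valve_fraction valve opening in `[0, 1]`.
#' @param dt step length in seconds, > 0.
#' @return The advanced `"gas_plant_state"`.
#' @export
plant_step <- function(state, params, valve_fraction, dt) {
  stopifnot(inherits(state, "gas_plant_state"),
            inherits(params, "gas_plant_params"))
  check_num(valve_fraction, "valve_fraction", lower = 0, upper = 1)
  check_num(dt, "dt", lower = .Machine$double.xmin)
  a <- params$injection_flow_Lps * valve_fraction / params$volume_L
  r <- a + params$leak_rate_per_s
  c0 <- state$co2_ppm
  if (r == 0) {
    c1 <- c0
  } else {
    cstar <- (a * params$source_ppm +
              params$leak_rate_per_s * params$ambient_ppm) / r
    c1 <- cstar + (c0 - cstar) * exp(-r * dt)
  }
  gas_plant_state(co2_ppm = clip(c1, 0, params$source_ppm),
                  time_s = state$time_s + dt)
}

#' Steady-state chamber concentration for a held valve position
#'
#' Algebraic fixed point of the mass balance: C* = (a*S + k*A) / (a + k)
#' with a = q*u/V. With the valve closed this is the ambient concentration
#' (leak-only equilibrium). If both the injection term and the leak rate
#' vanish the plant has no attractor; the ambient concentration is returned
#' by convention with attribute `degenerate = TRUE`.
#'
#' @inheritParams plant_step
#' @return Equilibrium concentration in ppm.
#' @export
plant_equilibrium <- function(params, valve_fraction) {
  stopifnot(inherits(params, "gas_plant_params"))
  check_num(valve_fraction, "valve_fraction", lower = 0, upper = 1)
  a <- params$injection_flow_Lps * valve_fraction / params$volume_L
  k <- params$leak_rate_per_s
  if (a + k == 0)
    return(structure(params$ambient_ppm, degenerate = TRUE))
  (a * params$source_ppm + k * params$ambient_ppm) / (a + k)
}
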