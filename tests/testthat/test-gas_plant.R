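# Chamber mass-balance model: exact integrator, equilibria, monotonicity.

test_that("a closed valve at ambient concentration is a stationary point", {
  p <- ref_plant()
  st <- gas_plant_state(co2_ppm = 450, time_s = 0)
  st2 <- plant_step(st, p, valve_fraction = 0, dt = 1)
  expect_equal(st2$co2_ppm, 450)
  expect_equal(st2$time_s, 1)
})

test_that("one open-valve second matches the closed-form solution", {
  p <- gas_plant_params(volume_L = 55, injection_flow_Lps = 0.012,
                        leak_rate_per_s = 0)
  st <- plant_step(gas_plant_state(50000), p, 1, 1)
  # frozen from 1e6 + (50000 - 1e6) * exp(-0.012/55)
  expect_equal(st$co2_ppm, 50207.2501173, tolerance = 1e-9)
})

test_that("the step integrator agrees with numerical ODE integration", {
  skip_if_not_installed("deSolve")
  p <- ref_plant()
  for (case in list(c(u = 1, c0 = 450, t = 60),
                    c(u = 0.3, c0 = 30000, t = 10),
                    c(u = 0, c0 = 80000, t = 60))) {
    st <- gas_plant_state(case[["c0"]])
    got <- plant_step(st, p, case[["u"]], case[["t"]])$co2_ppm
    want <- ode_oracle(case[["c0"]], case[["u"]], p, case[["t"]])
    expect_equal(got, want, tolerance = 1e-8)
  }
})

test_that("stepping composes as a semigroup: dt1 then dt2 equals dt1+dt2", {
  p <- ref_plant()
  set.seed(42)
  for (i in 1:20) {
    c0 <- runif(1, 450, 90000)
    u <- runif(1)
    dt1 <- runif(1, 0.01, 30)
    dt2 <- runif(1, 0.01, 30)
    st <- gas_plant_state(c0)
    one <- plant_step(st, p, u, dt1 + dt2)$co2_ppm
    two <- plant_step(plant_step(st, p, u, dt1), p, u, dt2)$co2_ppm
    expect_equal(two, one, tolerance = 1e-9)
  }
})

test_that("concentration moves monotonically toward the held-valve equilibrium", {
  p <- ref_plant()
  cstar <- plant_equilibrium(p, 1)
  # rising leg, valve open below equilibrium
  st <- gas_plant_state(450)
  prev <- 450
  for (i in 1:50) {
    st <- plant_step(st, p, 1, 1)
    expect_gt(st$co2_ppm, prev)
    expect_lt(st$co2_ppm, cstar)
    prev <- st$co2_ppm
  }
  # falling leg, valve closed above ambient
  st <- gas_plant_state(60000)
  prev <- 60000
  for (i in 1:50) {
    st <- plant_step(st, p, 0, 10)
    expect_lt(st$co2_ppm, prev)
    expect_gt(st$co2_ppm, p$ambient_ppm)
    prev <- st$co2_ppm
  }
})

test_that("equilibrium is the algebraic steady state and long runs reach it", {
  p <- ref_plant()
  expect_equal(plant_equilibrium(p, 0), 450)
  expect_equal(plant_equilibrium(gas_plant_params(injection_flow_Lps = 0), 1),
               450)
  # frozen from (a*1e6 + k*450)/(a + k), a = 0.012/55, k = 5e-5
  expect_equal(plant_equilibrium(p, 1), 813643.220339, tolerance = 1e-9)
  st <- gas_plant_state(450)
  st <- plant_step(st, p, 1, 1e6)  # hold the valve open for ~12 days
  expect_lt(abs(st$co2_ppm - plant_equilibrium(p, 1)), 0.1)
})

test_that("a valve held open with no leak saturates at the pure source", {
  p <- gas_plant_params(leak_rate_per_s = 0)
  st <- plant_step(gas_plant_state(450), p, 1, 1e7)
  expect_equal(st$co2_ppm, 1e6, tolerance = 1e-6)
})

test_that("degenerate and invalid inputs are rejected or flagged", {
  p <- ref_plant()
  expect_error(plant_step(gas_plant_state(450), p, 1, 0), "dt")
  expect_error(plant_step(gas_plant_state(450), p, 1.5, 1), "valve_fraction")
  expect_error(plant_step(gas_plant_state(450), p, NaN, 1), "valve_fraction")
  expect_error(gas_plant_params(volume_L = -1), "volume_L")
  dead <- gas_plant_params(injection_flow_Lps = 0, leak_rate_per_s = 0)
  eq <- plant_equilibrium(dead, 0)
  expect_equal(as.numeric(eq), 450)
  expect_true(isTRUE(attr(eq, "degenerate")))
})
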