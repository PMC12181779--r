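# The three control laws: threshold switching, timed pulses with lockout,
# and discrete PID with the proportional-valve current map.

test_that("threshold control opens strictly below setpoint minus hysteresis", {
  cfg <- tc_config(setpoint_ppm = 50000, hysteresis_pct = 0.5)
  expect_equal(cfg$hysteresis_ppm, 250)
  expect_equal(tc_decide(49600, cfg), "open")
  expect_equal(tc_decide(49800, cfg), "closed")
  expect_equal(tc_decide(49750, cfg), "closed")  # tie at threshold closes
  # pure function: repeated calls agree
  expect_identical(tc_decide(49600, cfg), tc_decide(49600, cfg))
})

test_that("timed-activation control picks pulse length by deviation", {
  cfg <- tac_config(setpoint_ppm = 50000, hysteresis_pct = 0.5,
                    open_short_s = 2, open_long_s = 6,
                    long_boundary_ppm = 1000)
  sched <- tac_scheduler_state()
  big <- tac_decide(30000, cfg, sched, 100)       # dev 20000 > boundary
  expect_equal(big$response, 6)
  small <- tac_decide(49700, cfg, sched, 100)     # dev 300 in (250, 1000]
  expect_equal(small$response, 2)
  none <- tac_decide(49900, cfg, sched, 100)      # dev 100 <= hysteresis
  expect_true(is.na(none$response))
  above <- tac_decide(51000, cfg, sched, 100)     # above setpoint: no vent
  expect_true(is.na(above$response))
})

test_that("timed-activation control enforces the post-response lockout", {
  cfg <- tac_config(setpoint_ppm = 50000, hysteresis_pct = 0.5)
  sched <- tac_scheduler_state()
  first <- tac_decide(30000, cfg, sched, 100)
  expect_equal(first$response, 6)
  expect_equal(first$sched$valve_open_until_s, 106)
  expect_equal(first$sched$last_response_end_s, 106)
  # still far below setpoint 30 s later: locked out
  locked <- tac_decide(30000, cfg, first$sched, 130)
  expect_true(is.na(locked$response))
  # lockout runs from the END of the response
  still <- tac_decide(30000, cfg, first$sched, 165)
  expect_true(is.na(still$response))
  free <- tac_decide(30000, cfg, first$sched, 166)
  expect_equal(free$response, 6)
})

test_that("at most one response occurs per lockout window on a decision stream", {
  cfg <- tac_config(setpoint_ppm = 50000, hysteresis_pct = 0.5)
  sched <- tac_scheduler_state()
  opens <- c()
  for (t in seq(0, 600, by = 2)) {
    d <- tac_decide(45000, cfg, sched, t)  # persistently low reading
    sched <- d$sched
    if (!is.na(d$response)) opens <- c(opens, t)
  }
  expect_true(all(diff(opens) >= cfg$post_response_wait_s))
})

test_that("discrete PID reproduces hand-computed responses of the control law", {
  valve <- proportional_valve_params()
  # proportional only: u = kp * e
  cfg <- pid_config(kp = 20, ki = 0, kd = 0, dt_s = 1, integral_limit = 1e9)
  st <- pid_state()
  out <- pid_step(50000, 49900, st, cfg)
  expect_equal(out$u, 2000)
  # printed gains, constant error 100 held 10 s: u = 20*100 + 0.6*1000
  cfg <- pid_config(kp = 20, ki = 0.6, kd = 0, dt_s = 1)
  st <- pid_state()
  for (i in 1:10) {
    out <- pid_step(50000, 49900, st, cfg)
    st <- out$state
  }
  expect_equal(out$u, 2600)
  # derivative term on a 10 ppm/s error ramp: u = kd * de/dt = 50
  cfg <- pid_config(kp = 0, ki = 0, kd = 5, dt_s = 1, integral_limit = 1e9)
  st <- pid_state(prev_error = 100)
  out <- pid_step(50000, 50000 - 110, st, cfg)
  expect_equal(out$u, 50)
  # no derivative kick: the first error initializes prev_error
  cfg <- pid_config(kp = 0, ki = 0, kd = 5, dt_s = 1, integral_limit = 1e9)
  out <- pid_step(50000, 30000, pid_state(), cfg)
  expect_equal(out$u, 0)
})

test_that("PID with zero integral and derivative gains is pure proportional", {
  cfg <- pid_config(kp = 20, ki = 0, kd = 0, dt_s = 1, integral_limit = 1)
  st <- pid_state()
  for (e in c(-5000, -1, 0, 0.5, 100, 20000)) {
    out <- pid_step(50000, 50000 - e, st, cfg)
    st <- out$state
    expect_equal(out$u, 20 * e)
  }
})

test_that("the integral accumulator is clamped for anti-windup", {
  cfg <- pid_config(kp = 0, ki = 0.6, kd = 0, dt_s = 1,
                    integral_limit = 500)
  st <- pid_state()
  for (i in 1:100) st <- pid_step(50000, 40000, st, cfg)$state
  expect_equal(st$integral_accum, 500)
  for (i in 1:100) st <- pid_step(50000, 60000, st, cfg)$state
  expect_equal(st$integral_accum, -500)
})

test_that("the proportional valve maps current linearly between 160 and 330 mA", {
  valve <- proportional_valve_params()
  cfg <- pid_config(output_to_mA = 0.01)
  expect_equal(control_to_valve_fraction(16000, valve, cfg), 0)   # 160 mA
  expect_equal(control_to_valve_fraction(8000, valve, cfg), 0)    # below onset
  expect_equal(control_to_valve_fraction(-500, valve, cfg), 0)    # negative u
  expect_equal(control_to_valve_fraction(24500, valve, cfg), 0.5) # 245 mA
  expect_equal(control_to_valve_fraction(33000, valve, cfg), 1)   # 330 mA
  expect_equal(control_to_valve_fraction(1e6, valve, cfg), 1)     # clamped
})
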