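# Closed-loop runner: wiring, timing rules, metrics, fault handling,
# determinism, and file round trips.

test_that("with the controller disabled the chamber stays at ambient", {
  sc <- scenario(controller = "none", duration_s = 300)
  tr <- run_closed_loop(sc)
  expect_true(all(abs(tr$true_ppm - 450) < 1e-9))
  expect_true(all(tr$valve_fraction == 0))
})

test_that("TAC traces honor the 60-s lockout and the 1020-ms read gate", {
  tr <- run_closed_loop(short_tac_scenario(duration_s = 1200))
  opens <- tr$time_s[grepl("open_for", tr$event)]
  expect_gt(length(opens), 2)  # the fill-up phase needs several pulses
  expect_true(all(diff(opens) >= 60))
  reads <- tr$time_s[!is.na(tr$measured_ppm)]
  expect_true(all(diff(reads) * 1000 >= 1020))
})

test_that("environmental checks run on their 30-s cadence", {
  sc <- scenario(controller = "tac", env_sensor = env_sensor_params(),
                 duration_s = 400)
  tr <- run_closed_loop(sc)
  checks <- tr$time_s[grepl("env_check", tr$event)]
  expect_true(all(abs(diff(checks) - 30) <= sc$tick_s))
  expect_equal(checks[1], 30)
})

test_that("an injected room leak latches the system and stops all injection", {
  sc <- scenario(controller = "tac", env_sensor = env_sensor_params(),
                 duration_s = 600,
                 faults = list(leak_at_s = 100, leak_ppm = 3000))
  tr <- run_closed_loop(sc)
  latch_t <- tr$time_s[grepl("latch", tr$event)]
  expect_length(latch_t, 1)
  # the latch lands on an env-check tick within ~2 lag constants of onset
  expect_gt(latch_t, 100)
  expect_lt(latch_t, 250)
  after <- tr$time_s > latch_t
  expect_true(all(tr$valve_fraction[after] == 0))
  expect_false(any(grepl("open_for", tr$event[after])))
})

test_that("a stuck chamber sensor freezes corrective action until it recovers", {
  sc <- short_tac_scenario(duration_s = 600)
  sc$faults <- list(stuck_at_s = 100)
  tr <- run_closed_loop(sc)
  freeze_t <- tr$time_s[grepl("\\bfreeze\\b", tr$event)]
  expect_length(freeze_t, 1)
  expect_true(freeze_t > 160 && freeze_t <= 170)  # > 60 s of identical reads
  after <- tr$time_s > freeze_t
  expect_true(all(tr$valve_fraction[after] == 0))
  # the frozen reading repeats verbatim
  ms <- tr$measured_ppm[after & !is.na(tr$measured_ppm)]
  expect_true(all(ms == ms[1]))
})

test_that("a pause press suspends injection for the full countdown", {
  sc <- short_tac_scenario(duration_s = 400)
  sc$faults <- list(pause_at_s = 100)
  tr <- run_closed_loop(sc)
  expect_true(any(grepl("pause_press", tr$event)))
  paused <- tr$time_s > 100 & tr$time_s <= 160
  expect_true(all(tr$valve_fraction[paused] == 0))
  # regulation resumes afterwards (the chamber is still far below setpoint)
  expect_true(any(tr$valve_fraction[tr$time_s > 160] > 0))
})

test_that("metrics on analytically constructed traces match closed forms", {
  flat <- structure(data.frame(time_s = 1:100, true_ppm = 50000,
                               measured_ppm = 50000, valve_fraction = 0,
                               event = ""),
                    class = c("co2_trace", "data.frame"))
  m <- fluctuation_metrics(flat, c(1, 100), setpoint_ppm = 50000,
                           hysteresis_ppm = 250)
  expect_equal(m$max_dev_from_mean_ppm, 0)
  expect_equal(m$pct_of_setpoint, 0)
  expect_equal(m$settling_time_s, 1)
  saw <- flat
  saw$measured_ppm <- 50000 + rep(c(-100, 100), 50)  # mean 50000 exactly
  m2 <- fluctuation_metrics(saw, c(1, 100), setpoint_ppm = 50000)
  expect_equal(m2$mean_ppm, 50000)
  expect_equal(m2$max_dev_from_mean_ppm, 100)
  expect_equal(m2$pct_of_setpoint, 0.2)
  expect_error(fluctuation_metrics(flat, c(50, 50), 50000), "window")
})

test_that("percent-of-setpoint uses half-up rounding to two decimals", {
  expect_equal(percent_of_setpoint(120, 10000), 1.2)
  expect_equal(percent_of_setpoint(145, 20000), 0.73)  # 0.725 rounds up
  expect_equal(percent_of_setpoint(260, 50000), 0.52)
  expect_equal(percent_of_setpoint(0, 50000), 0)
})

test_that("identical scenario and seed give byte-identical traces", {
  sc <- short_tac_scenario(duration_s = 300)
  t1 <- run_closed_loop(sc)
  t2 <- run_closed_loop(sc)
  expect_identical(trace_hash(t1), trace_hash(t2))
  noisy <- scenario(controller = "tac", duration_s = 300, seed = 9,
                    sensor = ndir_sensor_params(noise_sd_ppm = 10))
  n1 <- run_closed_loop(noisy)
  n2 <- run_closed_loop(noisy)
  expect_identical(trace_hash(n1), trace_hash(n2))
  noisy$seed <- 10L
  n3 <- run_closed_loop(noisy)
  expect_false(identical(trace_hash(n1), trace_hash(n3)))
})

test_that("traces round-trip through CSV with one row per tick", {
  sc <- short_tac_scenario(duration_s = 120)
  tr <- run_closed_loop(sc)
  f <- tempfile(fileext = ".csv")
  on.exit(unlink(f))
  write_trace(tr, f)
  back <- read_trace(f)
  expect_equal(nrow(back), sc$duration_s / sc$tick_s)
  expect_equal(back$true_ppm, tr$true_ppm, tolerance = 1e-12)
  expect_equal(back$event, tr$event)
})

test_that("scenario files round-trip and reproduce the identical trace", {
  sc <- short_tac_scenario(duration_s = 200)
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  write_scenario(sc, f)
  sc2 <- read_scenario(f)
  expect_identical(trace_hash(run_closed_loop(sc)),
                   trace_hash(run_closed_loop(sc2)))
})

test_that("invalid scenario files are rejected with itemized messages", {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  cfg <- list(setpoint_ppm = 50000,
              plant = list(injection_flow_Lps = 0.012, source_ppm = 1e6,
                           leak_rate_per_s = 5e-5, ambient_ppm = 450),
              sensor = unclass(ndir_sensor_params()),
              controller = "tac", duration_s = 100)
  jsonlite::write_json(cfg, f, auto_unbox = TRUE)
  expect_error(read_scenario(f), "volume_L")
  cfg$plant$volume_L <- 55
  cfg$frobnicate <- 1
  jsonlite::write_json(cfg, f, auto_unbox = TRUE)
  expect_error(read_scenario(f), "frobnicate")
  cfg$frobnicate <- NULL
  cfg$duration_s <- NULL
  jsonlite::write_json(cfg, f, auto_unbox = TRUE)
  expect_error(read_scenario(f), "duration_s")
})
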