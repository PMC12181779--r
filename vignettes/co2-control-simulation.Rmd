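---
title: "Simulating closed-loop CO2 regulation of an incubator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating closed-loop CO2 regulation of an incubator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(co2reg)
```

`co2reg` models a low-cost CO₂ setpoint regulator for microbial
incubators — solenoid valve, NDIR sensor, microcontroller firmware — and
the chamber it regulates, so the whole closed loop can be studied in
software. This vignette is the package's account of the models, the
parameters that matter, the numerical choices, and what the simulation
does and does not tell you about real hardware.

## The plant: a well-mixed chamber

The chamber is a single well-mixed volume $V$ (litres). Pure CO₂
(concentration $S = 10^6$ ppm) enters at volumetric flow $q u$, where
$u \in [0,1]$ is the valve opening fraction, and the chamber exchanges
air with the room (ambient $A$ ppm) at a first-order leak rate $k$
(s⁻¹):

$$\frac{dC}{dt} = \frac{q u}{V}\,(S - C) \; - \; k\,(C - A).$$

For constant $u$ this is linear with relaxation rate $r = qu/V + k$ and
fixed point $C^\* = (quS/V + kA)/r$, so `plant_step()` advances the state
by the exact solution $C(t{+}\Delta t) = C^\* + (C - C^\*)e^{-r\Delta t}$
rather than an Euler step. The update is unconditionally stable at the
1-s control tick, and stepping $\Delta t_1$ then $\Delta t_2$ equals
stepping $\Delta t_1 + \Delta t_2$ exactly — a property the tests check
directly, alongside agreement with numerical ODE integration (`deSolve`)
to $10^{-9}$ relative error.

**Reference parameterization.** $V = 55$ L (mid-range of a typical
50–60 L bench incubator), $q = 0.012$ L/s, $k = 5\times10^{-5}$ s⁻¹,
$A = 450$ ppm (the ambient off-state a run starts from). The device's
documented design fixes the incubator size and the off-state but not
the injection flow or leakage, so $q$ and $k$ are calibration choices:
they make one short valve pulse move the chamber by a few hundred ppm and
unaided decay at 5% CO₂ a few ppm per second, consistent with corrective
cycles at least 60 s apart. They are held fixed across every scenario in
the package and are not tuned per setpoint. An optional biological CO₂
uptake term would enter exactly like the leak; cultures' consumption is
not quantified, so it defaults to absent.

## The sensor: first-order lag plus read gating

The chamber sensor (MH-Z16 class) reports 0–100,000 ppm with a response
time specified as $T_{90} < 30$ s. We model the response as a first-order
lag with time constant $\tau = T_{90}/\ln 10 \approx 13.03$ s, using the
stated upper bound $T_{90} = 30$ s as the default (worst case); after
exactly $T_{90}$ seconds of a held step the lagged value has covered 90%
of it, which the tests verify to $10^{-6}$ relative. Readings are the
lagged value times $(1 + \text{bias})$, plus optional Gaussian noise,
clipped to the reporting range and rounded to integer ppm as the serial
protocol would print them.

The stated 6% sensor error is modelled as a constant multiplicative
*bias* (accuracy), not per-read noise (precision): documented stability
traces are smooth, and a constant of-reading bias is the interpretation
that leaves closed-loop dynamics unchanged while shifting the reported
level. Whether the 6% is of-reading or full-scale is not stated; we chose
of-reading. Reference scenarios set bias and noise to zero so runs are
deterministic.

Reads are gated: at least 1020 ms must pass between accepted reads
(shorter intervals give unreliable values on the real sensor), and a
too-early attempt is a *refusal* — a normal outcome, not an error. With
the 1-s control tick this means measurements land every 2 s. The sensor
also supports a stuck fault: the reported value freezes while the
internal lag keeps tracking, which is exactly the failure the firmware's
stuck-sensor safety is meant to catch. The optional room sensor
(MH-Z19E class) uses a 400–5000 ppm range and a slower 60-s $T_{90}$; its
cadence is set by the 30-s safety check rather than the control loop.

## The three control laws

All three act one-sidedly: there is no exhaust valve, so nothing can be
done about a reading above setpoint except waiting for the leak.

**Threshold control (TC).** Open iff the reading is strictly below
`setpoint − hysteresis`; at or above that threshold ("surpassing" it) the
valve closes, so ties close. The hysteresis is specified as a percent of
the setpoint (0.5% at the 5% setpoint, i.e. 250 ppm). We read the rule as
single-threshold switching — open below, closed at or above the same
threshold; the alternative two-threshold reading (close only at the
setpoint itself) was considered and not adopted.

**Timed-activation control (TAC).** On each accepted reading, if the
lockout has expired and the deviation below setpoint exceeds the
hysteresis band, the valve opens for a *fixed* duration: `OpenShort` for
moderate deviations, `OpenLong` beyond a boundary. After the pulse ends,
a `post_response_wait_s` lockout (≥ 60 s) blocks further responses so the
slow sensor can register the change. Two conventions are ours: the
trigger threshold mirrors the TC threshold (`setpoint − hysteresis`; the
firmware description only says pulse length scales with distance from
setpoint), and the long/short boundary defaults to 4× the hysteresis
band — it must exceed the band, and 4× keeps steady-state cycles on the
short pulse while the initial fill-up uses the long one.

**PID.** Discrete PID on the error $e = \text{setpoint} -
\text{measurement}$, with the hand-tuned gains $K_p = 20$, $K_i = 0.6$,
$K_d = 5$ as defaults. Numerical choices: the integral accumulator is
clamped (anti-windup) at the value whose $K_i$-weighted contribution
equals full-scale valve current (the hardware behaves windup-free but no
mechanism is described, so clamping is our choice); the derivative acts
on the error, with the previous error initialized to the first error so
startup produces no derivative kick. The control signal maps to coil
current at 0.01 mA per unit of $u$ (the hardware maps $u$ to a PWM
current without stating a scale) and the proportional valve's flow is
linear in current between the 160 mA opening onset and the 330 mA full
flow, clamped outside.

## The safety state machine

Three independent guards gate all corrective action:

* **pause** — a button press suspends action for `pause_duration_s`
  (default 60 s) so the incubator can be opened without triggering a CO₂
  burst; a second press restarts the countdown (restart rather than
  ignore is our choice; the behavior is unspecified).
* **freeze** — the identical integer reading persisting for more than
  `stuck_window_s` (default 60 s) freezes action; any differing reading
  clears it automatically.
* **latch** — every `env_check_period_s` (default 30 s) the room reading
  is checked; above `env_threshold_ppm` the valve is forced closed and
  the system latches until an explicit reset, emulating the required
  reboot after a leak. No numeric threshold is documented; the 2000 ppm
  default sits above typical occupied-room levels and well below the
  5000 ppm occupational exposure limit.

The harness enforces, and the tests verify mechanically, that no
valve-opening occurs while any guard is active and that a latch zeroes
all subsequent valve-open time.

## Calibration and persistence

Setpoints span 1–6% CO₂. Three validated rows anchor the setpoint →
(hysteresis, OpenLong, OpenShort) mapping — 1% → (2%, 4 s, 1 s),
2% → (1%, 4 s, 1 s), 5% → (0.5%, 6 s, 2 s) — and `calibrate_setpoint()`
interpolates piecewise-linearly between anchors and clamps setpoints
above 5% to the 5% row (operation is validated up to 6% but no separate
row exists). The interpolation rule is a convention: only the anchors are
authoritative, the released firmware's exact adjustment formula lives in
its source, not in any documented table. Opening times scale linearly with
chamber volume about the 55 L reference (a 110 L incubator doubles them);
the hysteresis band is a sensor/controller property and does not scale.
Settings round-trip through a small JSON file standing in for the
firmware's non-volatile memory; a missing file yields the factory
defaults (5%, 0.5%, 6 s, 2 s, 60 s pause) and a corrupt one warns and
falls back to the same defaults.

## The scenario runner and metrics

`run_closed_loop()` ticks at 1 s. Within each tick the plant and sensor
lag advance — sub-stepped at 0.1 s whenever the valve is open, since 1–6 s
pulses need sub-tick resolution — then a read is attempted under the
1020-ms gate, safety checks run (stuck detection on every accepted read,
the environmental check on its 30-s cadence), and finally the controller
acts if every guard is clear. Traces have one row per tick; the measured
column is filled only on ticks whose read was accepted. Runs are
deterministic given the scenario and seed — noise-free reference runs are
deterministic outright — and trace hashing (MD5 of the canonical CSV
rendering) makes that checkable.

`fluctuation_metrics()` characterizes a window (the final 30 minutes by
default, excluding the fill-up transient) by the maximal deviation of the
measured signal **about the window mean**, expressed also as a percent of
the setpoint with half-up rounding to two decimals (so 145 ppm at 2% is
0.725% and prints as 0.73). Mean-centering rather than
setpoint-centering is an interpretation we adopted deliberately: a
one-sided below-threshold trigger makes the loop ride slightly below its
setpoint, and the mean-centered metric is the one that maps the device's
documented ppm and percent figures onto each other consistently at all
three setpoints (120 ppm ↔ 1.2% at 1%, 145 ppm ↔ 0.73% at 2%,
260 ppm ↔ 0.52% at 5%). Settling time is the first instant after which
the measurement stays within ±2 hysteresis bands of the setpoint for the
rest of the run.

Problem sizes: reference stability runs are 120 simulated minutes
(7200 ticks) with metrics over minutes 90–120; the PID steady-state check
uses a 3-hour run. These lengths bracket the documented one-hour
characterization runs while leaving a generous margin past the settling
transient.

```{r reference-run}
sc <- reference_scenario(setpoint_pct = 5)
trace <- run_closed_loop(sc)
fluctuation_metrics(trace, window = c(5400, 7200))
```

## What the simulation does and does not show

The scenario generator emulates: the mixing dynamics of a leaky chamber,
the sensor's slow first-order response, the read-rate limit, the firmware
timing rules (pulse durations, 60-s lockout, 30-s environmental cadence,
pause countdown), and sensor faults. It does not emulate: spatial
gradients, temperature or pressure dependence, humidity interactions,
valve wear beyond actuation counting, NDIR optics, warm-up transients, or
the sensor's zero-calibration routine. Passing tests therefore validate
the control *logic* under an idealized plant, not the hardware's absolute
performance figures.

One limitation deserves emphasis. The real sensor updates its reported
value in discrete steps roughly every 30 s — closer to a zero-order hold
than to a smooth first-order lag. Under the smooth lag used here, a
bang-bang controller polling every second closes the valve within a
couple of seconds of the measured signal re-crossing its threshold, so
threshold control simulates almost as stably as timed-activation control.
On hardware, where the held reading keeps the valve open for tens of
seconds past the true crossing, bang-bang fluctuates an order of
magnitude worse — that is precisely the regime the timed-activation
design exists for. The strategy comparison in this package should
therefore be read as *TAC and PID are insensitive to the sensor's
registration behavior; threshold control is not*, rather than as a
quantitative reproduction of the hardware comparison. PID's documented
settling shape (stabilizing just below setpoint before converging) is
likewise not quantitatively reproducible on this idealized plant.

```{r comparison, eval = FALSE}
compare_strategies(sc)
```

## Degenerate inputs and tie-breaks

A plant with zero injection and zero leak has no attractor; its
equilibrium query returns the ambient concentration flagged as
degenerate. A reading exactly at the trigger threshold closes (TC) or
does nothing (TAC). Stuck detection compares integer-rounded readings for
exact equality, matching the integer serial protocol. Refused reads
change no state. Scenario files are schema-checked: unknown keys are
rejected and missing required fields are named, all problems reported
together.
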