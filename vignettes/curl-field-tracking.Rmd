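---
title: "Tracking and force control in a curl field: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking and force control in a curl field: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(curltrack)
library(dplyr)
```

`curltrack` studies a hybrid sensorimotor task: a subject tracks a target
moving along a figure eight while a robot pushes the hand sideways with a
force proportional to movement speed. The package provides the task model,
a simulated subject that stands in for human recordings, and the complete
set of tracking and force-control indicators, including the catch-trial
decomposition that splits disturbance compensation into a voluntary force
component and a limb-stiffness component.

## The task model

The target moves on a 1:2 Lissajous figure,

$$x = A\sin\alpha,\qquad y = B\sin 2\alpha,$$

with $A = 15.7$ cm and $B = 9$ cm, giving a closed path of about 102 cm.
Under errorless tracking the phase advances at $2\pi/T$ with $T = 8$ s, so
the tangential speed spans 8.3–18.8 cm/s, the acceleration never exceeds
0.3 m/s², and the speed and absolute-curvature profiles are strongly
anti-correlated ($|r| = 0.91$) — the familiar speed–curvature coupling of
curved movements. These closed-form quantities are the package's built-in
benchmarks:

```{r}
ideal_lap_summary(task_config())
```

The target is *error-gated*: its angular speed is scaled by
$\gamma(e) = 1 - (10s^3 - 15s^4 + 6s^5)$ with $s = e/D$, a minimum-jerk
step from 1 to 0 over $[0, D]$, $D = 6$ cm. The gain is exactly 0.5 at 3 cm
and the target stops and waits whenever the tracking error reaches $D$.
This form is the unique quintic that is C² at both ends and symmetric
about $D/2$, which is why it is adopted here.

The disturbance is a curl viscous field,
$F = b\,(v_y, -v_x)$ with $b = 100$ N·s/m: the velocity rotated 90°
clockwise, i.e. always to the right of travel. It does no mechanical work
($F \cdot v = 0$) and its magnitude tracks the speed profile, which is what
couples the force sub-task to the tracking sub-task. Whether the
experimental field acted on the measured hand velocity or on the target's
velocity cannot be settled from the task description alone — the two
coincide under errorless tracking — so `task_config(field_velocity_source=)`
supports both, defaulting to hand velocity (the standard curl field).

## The simulated subject

No human recordings are distributed with this problem, so the package
includes a generative stand-in whose every parameter is explicit. It is a
minimal mechanism for the observed phenomenology, not a claim about neural
control:

* **Arm impedance.** The hand is a point mass $m = 2$ kg (arm plus handle)
  coupled to a planned reference through endpoint stiffness
  $K = 600$ N/m and critical damping $B = 2\sqrt{Km}$. Criticality keeps
  the catch-trial readout free of oscillatory artifacts; the quasi-static
  analysis below ignores damping anyway.
* **Intermittent planning.** At 1.6 Hz the subject commits to a
  minimum-jerk segment from its current state to the target's predicted
  position one replan interval ahead. The landing point carries only a
  fraction (`hold_fraction_vel`, default 0.8) of the predicted target
  velocity — a partial "step-and-hold". This value was fixed by matching
  three qualitative signatures at once: the submovement count rises from
  ~13 per lap without the field to ~20 with it, the hand-minus-target
  residual speed shows a clear spectral peak at the 1.6 Hz replanning
  rate, and the catch-trial estimators stay unbiased. Fully
  velocity-matched segments (fraction 1) are too smooth to segment; a full
  hold (fraction 0) pulses so hard that the quasi-static force balance
  degrades.
* **Planning noise.** Each landing point is perturbed by isotropic
  Gaussian noise with 2 mm sd — the scale of the task's implicit 2 cm
  accuracy demand divided by the ~10 corrective submovements a lap allows.
* **Feedforward compensation.** An adapted subject commands
  $F_C = -g\,b\,(v_{r,y}, -v_{r,x})$ computed from the *planned reference*
  velocity, with gain $g \in [0,1]$ (`compensation_gain`, default 0.8).
  Using the planned rather than the measured velocity matters: a command
  driven by measured velocity reacts to the catch-trial rebound itself and
  inflates the final lateral deviation by ~30%, which is neither how a
  feedforward internal model works nor compatible with an unbiased
  stiffness estimate. The command follows the subject's *belief*, so it
  stays on during the unannounced 0.5 s catch windows.
* **Adaptation dynamics.** The commanded gain ramps toward its asymptote
  with lap constant `tau_adapt` (default 9.4 laps) while the field is on
  and decays with `tau_washout` (default 1.3 laps) when it is removed, a
  first-order stand-in for trial-by-trial learning that is sufficient to
  exercise the learning-curve fitter. `simulate_session(start_adapted=)`
  skips the ramp when steady-state estimators are the object of study.

The protocol mirrors the experimental one: FA1, FA2 (field off), FF1, FF2
(field on), WO (field off), each run to 30 proper turns (laps under 12 s),
with 6 catch trials per field set, triggered at the figure's central
crossing only when the tracking error there is below 2 cm, half on
rightward and half on leftward crossings.

## Kinematics and indicators

Raw 100 Hz positions are smoothed with a 6th-order Savitzky–Golay filter,
window 170 ms (17 samples, ≈11 Hz cut-off); the same local polynomial fit
supplies both derivatives. The first and last half-window of every lap is
excluded from indicator averages so that each lap's numbers depend only on
its own samples. Catch-trial windows are also excluded from the ordinary
lap indicators, because the force balance inside them is deliberately
different; they are analysed by the catch-trial module instead.

Per lap the package reports: duration DUR and the <12 s proper flag; the
tracking error δ with its longitudinal (δ_l, positive = hand ahead) and
normal (δ_n, positive = hand right of travel) components; the figural
error FE (a symmetrized mean point-to-polyline distance between the hand
and target paths — symmetrized so it is a true metric and segment-based so
it is insensitive to resampling); the submovement count NP (speed-profile
minima with a prominence of at least 2% of the lap's peak speed, counted
circularly since a lap is a closed circuit — the errorless lap then gives
exactly 4); the speed–|curvature| correlation CC; the lateral deviation LD
from the nominal path; and the force–movement correlation
FMC = |corr(speed, LD)|.

Two conventions deserve a note. First, the sign convention: the source
descriptions of δ_n and of LD_ini/LD_fin are internally inconsistent, so
one convention is applied uniformly — *rightward of travel is positive* —
under which the field pushes δ_n and LD positive and catch trials drive LD
negative. Second, LD projects the hand onto a dense polyline of the ideal
path; the figure eight self-intersects at the origin, so the projection is
restricted to a quarter-turn window around the target's own phase angle,
which resolves the branch ambiguity at the crossing. The prominence floor
on NP and the spectral rule in `dominant_frequency()` (Welch-averaged
periodogram, peak above 0.5 Hz, absent unless it exceeds 3× the band's
median power) are regularizations required for finite, noise-stable
counts; both are exposed in the configuration.

## Catch-trial decomposition

During a catch trial the field is silently removed for 0.5 s at the
crossing. Writing the quasi-static balance normal to the path at
switch-off onset ($t_0$) and at the end of the window ($t_F$):

$$F_D = F_C + K\,LD_{ini}, \qquad 0 = F_C + K\,LD_{fin},$$

with $F_D = b\,|v(t_0)|$ known. Solving,

$$K = \frac{F_D}{LD_{ini} - LD_{fin}},\qquad F_C = -K\,LD_{fin},\qquad
PAC = \frac{F_C}{F_D} = \frac{-LD_{fin}}{LD_{ini}-LD_{fin}}.$$

PAC — the proportion of active compensation — is the fraction of the
disturbance balanced by the voluntary command rather than by limb
stiffness. The estimator inherits the quasi-static first-order
approximation as-is: no damping or inertia correction. Simulator
round-trips show PAC recovers the configured gain to within ±0.03 across
$g \in \{0.5, 0.8, 1.0\}$. The stiffness estimate reads out the
*effective* quasi-static stiffness, which sits 10–20% below the spring
constant: every replan re-anchors the reference at the (deviated) hand, and
that intermittent re-anchoring adds compliance the static spring does not
have. This is a real property of intermittent control, not an estimator
defect — the same bias would affect a human arm measured this way.
Singular trials ($LD_{ini} = LD_{fin}$) are flagged, never silently
dropped, and trials whose onset error exceeds 2 cm are rejected because
the quasi-static premise fails there.

## Learning curves

Across-lap error decay is fitted as
$\delta(k) = A_0 e^{-k/\tau} + A_1$ with `minpack.lm::nlsLM`,
multi-started from $\tau \in \{2, 5, 15\}$ laps, $A_1$ initialized at the
mean of the last five laps and $A_0$ at the first lap's excess; lowest
residual sum of squares wins. A vanishing fitted amplitude leaves $\tau$
unidentified and the fit is flagged. On a single noisy 60-lap series with
lap noise of 20% of $A_0$, *no* estimator resolves $\tau$ to ±30% much
more than ~80% of the time — a profiled grid-search oracle and the
nonlinear fitter agree on this rate, and the test suite asserts their
parity rather than an unattainable coverage. The reference procedure fits
the *population-mean* curve (nine subjects averaged), where ±30% recovery
succeeds in essentially every replicate; that is the configuration the
acceptance checks exercise.

## What the generator does and does not emulate

The simulator reproduces: the 100 Hz log format and lap structure;
intermittent submovements at the replanning rate; the rightward lateral
bias under the field ((1−g)·F_D/K ≈ 6 mm at the defaults, against ~7 mm
reported for humans); unbiased lateral error without the field; the NP
increase and CC decrease under the field; catch-trial overshoot to the
left of the path; and exponential adaptation and wash-out with the
configured lap constants.

It does not emulate: baseline skill acquisition during familiarization
(FA phases are stationary — the ~4.6-lap familiarization constant of human
data has no counterpart here); the human magnitude of baseline tracking
error (≈3 mm simulated vs ≈16 mm human — the planner predicts the target
better than people do); and the human degree of decoupling between speed
and lateral deviation. On that last point: with 80% compensation the
residual lateral force is still proportional to speed, and the simulator's
clean dynamics leave FMC ≈ 0.4, where humans show ≈ 0.08 — human lateral
deviation is dominated by motor noise that this generator intentionally
lacks. FMC does fall sharply (to ≈ 0.1) at full compensation, which the
tests assert instead of a human-matched absolute value. Passing tests
therefore validate the estimators and the mechanism, not a claim that the
generator is statistically indistinguishable from human data.

## Numerical choices and problem sizes

Explicit choices, all visible in the code: target phase integrated by
explicit Euler at the 100 Hz task rate (errors far below the 2 cm task
resolution); arm dynamics by semi-implicit Euler, stable at
$\omega_n \Delta t \approx 0.17$; curvature flagged invalid below a 1 mm/s
speed floor; LD projection onto a 720-point path polyline with
segment-projection refinement (≈3 µm worst-case error); stalled-target
frames inherit the last valid travel frame; ties in peak location resolve
to the first index. The test suite runs sessions of 12–15 proper turns per
phase and the acceptance checks use three seeds per compensation gain and
20,000-point quadrature for the ideal-lap analytics; these sizes were
chosen so the whole suite completes in about a minute while keeping every
Monte-Carlo assertion comfortably away from its threshold.

```{r, fig.height = 3.5}
proto <- session_protocol(n_proper_turns = 6, catch_trials_per_field_set = 3)
log <- simulate_session(proto, subject_params(seed = 7), task_config())
autoplot(lap_table(log))
```

## Known limitations

The impedance model is a point mass with isotropic, constant stiffness; no
muscle-level or posture-dependent structure. Adaptation is a deterministic
first-order gain ramp, not error-driven learning, so the simulated
learning curve's shape is exponential by construction — recovering its lap
constant validates the fitter, not a learning theory. The catch-trial
estimator assumes the commanded force is constant across the 0.5 s window;
the simulator's command varies with the planned speed over that window,
which contributes a small part of the stiffness underestimate discussed
above. The G1/G2 visual-background distinction of the original protocol is
recorded in configuration but has no behavioral effect here.
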