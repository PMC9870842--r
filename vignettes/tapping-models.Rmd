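---
title: "Modelling tapping on jittering, moving and accelerating targets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling tapping on jittering, moving and accelerating targets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tapsim)
```

## The task and the models

`tapsim` simulates and analyses a rapid interception task: a participant
taps with the index finger on a disk that moves laterally on a 120 Hz
display, its position perturbed every 8.3 ms by a small step. Depending on
the design, the steps form a pure random walk (a jittering but otherwise
static target), a rightward drift with jittered step sizes, or a smooth
constant acceleration. The finger is tracked at 500 Hz and the tap is
detected from the impact deceleration.

Three model components are chained per trial:

1. **Delayed extrapolation.** At time $t$ the hand is guided towards
   $A_t = T_{t-\delta} + v_{t-\delta}\,(t_{tap} - (t - \delta))$: the target
   position one visuomotor delay $\delta$ earlier, extrapolated to the
   anticipated tap time with a velocity estimate. Assuming the aim point is
   reached, the predicted tapping error is
   $A_{tap} - T_{tap} = T_{tap-\delta} - T_{tap} + v_{tap-\delta}\,\delta$.
   $\delta$ is implemented as exactly 12 display frames (100 ms).

2. **Leaky velocity accumulation.** The estimate is updated once per
   displayed step, $v_s = (1 - w)\,v_{s-1} + w\,v_{step}$, with $w = 0.02$
   per frame by default ($w = 0.15$ for the fast variant). At 2% per frame
   the estimate needs 35 frames (about 292 ms) to move halfway to a new
   constant velocity, and the final value of one trial seeds the next
   (`run_trial_accumulation`), which is what couples consecutive trials.

3. **Error-correction learning with forgetting.** Between trials a spatial
   correction $C^s$ (mm) and a temporal correction $C^t$ (s) adjust the aim
   point, $A_{t,i} = T_{t-\delta} + v_{t-\delta}(t_{tap} + C^t_i - (t -
   \delta)) + C^s_i$. After every tap each correction is retained at 95%
   and adjusted against the trial's error: $C^s_{i+1} = 0.95\,C^s_i -
   0.25\,(A_{tap} - T_{tap})$ and $C^t_{i+1} = 0.95\,C^t_i -
   0.15\,(t_{passed} - t_{tap})$, where $t_{passed}$ is when the target
   passed (or would have passed) the tapped position. Both start at zero at
   each session start.

Two response models turn target steps into finger kinematics for the
synthetic 500 Hz data: a minimum-jerk correction,
$\dot{x} = 30\,D\,t^2(1-t)^2/T$ with $t$ the elapsed fraction of the
available time $T$, and a mass-spring-damper
$\ddot{x} + b\dot{x} + kx = 0$ with $b = 75\,\mathrm{s}^{-1}$ and a
stiffness $k = 3800 - 16\,T\ \mathrm{s}^{-2}$ ($T$ in ms) that grows as
less time remains. The spring model is underdamped — it overshoots — for
$T$ below $T^* = (3800 - 75^2/4)/16 \approx 149.6$ ms.

## Units, conventions and key parameters

Positions are in mm (screen centre = lateral origin, rightward positive),
times in seconds, speeds in mm/s internally (reported as cm/s where that is
the conventional unit). The main tunables:

| parameter | default | meaning |
|---|---|---|
| `w` | 0.02 (0.15 fast) | fraction of each step's velocity entering the estimate |
| `delay_frames` | 12 | visuomotor delay in 120 Hz frames (100 ms) |
| `retention` | 0.95 | per-trial retention of each learned correction |
| `spatial_rate`, `temporal_rate` | 0.25, 0.15 | fraction of each error corrected |
| `b`, `k(T)` | 75 s⁻¹, 3800 − 16 T | response-model damping and stiffness |
| `noise_sd` | 0.5 mm | white positional noise on synthetic finger samples |

None of these is fitted anywhere in the package; they are fixed model
constants, and the session simulator only exposes them as configuration.

## What the generators emulate

`make_random_walk` produces the ±5/3 mm per-frame jitter (a 20 cm/s step
speed). `make_drifting_walk` adds a 5 mm rightward displacement per frame
on average; `variability_scheme` supplies the four jitter amplitudes
(per-frame speeds of {60}, {50, 70}, {40, 80}, {25, 95} cm/s), and a
deterministic 12-frame prefix gives the designs in which the first 100 ms
are uniformly fast (80 cm/s from −220 mm) or slow (40 cm/s from −180 mm),
meeting at −140 mm. `accel_spec` reconstructs the eight
accelerating/decelerating kinds from their printed constraints: ±400 mm/s²
along the motion, start 300 mm (slow) or 400 mm (fast) from the centre on
the side opposite the motion, and an initial speed solved so the target is
300 mm past the centre at 700 ms. The reconstruction reproduces the quoted
~14 cm/s difference between the speed classes exactly (100 mm / 0.7 s).
Frame steps use the continuous velocity at the frame midpoint, which makes
the discrete positions coincide with the continuous kinematics at every
frame time, so the 700 ms constraint holds to machine precision.

Trial durations are the one study condition the package cannot take from
data: the simulator draws each trial's tap frame from a normal distribution
whose mean is the sum of the printed reaction- and movement-time means and
whose SD combines their SDs, rounded to frames and clipped to 24–120 frames
(`sample_tap_frame`). This replaces the resampling of real trial durations.
It matters: the slow-accumulation acceleration-session error is sensitive
to the assumed durations (about +0.3 mm per +10 ms of mean duration, see
`mean_shift_ms` in `simulate_experiment5`), and the printed statistics are
averages of participant medians, which for right-skewed duration
distributions understate the mean. The fast-accumulation (w = 0.15)
prediction is essentially insensitive to this choice because the estimate
reaches its within-trial steady state either way.

With the default conditions the simulator yields, per 200 simulated
sessions: a previous-trial velocity influence of ≈1.3 mm (w = 0.02,
drifting-target sessions of 500 trials), and mean
ignoring-acceleration-signed errors of ≈6.5–6.9 mm (w = 0.02) and
≈4.04 mm (w = 0.15) for the acceleration sessions. The learning-enabled
model declines across bins only in the acceleration- and error-grouped
blocks, and in the alternating-blocks scenario errors fall within each
12-trial block while the 0.95 retention keeps the two corrections bounded
(with retention 1.0 they drift off together — the spatial and temporal
corrections compensate for each other, and the run becomes unstable).

## Synthetic finger data and what the pipeline tests show

`synthesize_trial` superposes one response per target step — each response
to the step's *deviation from the expected step*, starting 100 ms after the
step with the time remaining until the tap as its available time — on a
minimum-jerk transport towards the target's expected tap position, plus a
stereotyped vertical reach that ends in an impact exceeding the 50 m/s²
detection threshold. The transport is deliberately independent of the
realized jitter; an earlier formulation that aimed the transport at the
trial's own mean step leaked part of each step's displacement into the
movement before the response latency and biased the recovered latency
downwards. Keeping the mean motion in the transport and only deviations in
the responses makes the step-triggered analysis (which differences two
trial sets) exact.

The stiffness law is only meaningful for $T \le 200$ ms (steps up to
300 ms before the tap, the analysed range); beyond that it approaches zero
stiffness at $T = 237.5$ ms and the response would never settle. Responses
to earlier steps therefore use the stiffness at the 200 ms cap
(`msd_T_cap_ms`), under which they settle well before the tap (slow
eigenvalue ≈ 9 s⁻¹), matching the observed full correction of early steps.

The analysis pipeline mirrors the laboratory one: 9-point second-order
Savitzky–Golay position/velocity estimates (coefficients from the `signal`
package; end samples use the off-centre rows of the projection matrix,
which stay exact on quadratics), impact-based tap detection with a
minimum-height fallback for gentle taps, the two exclusion rules (taps
later than 700 ms; >20 ms of missing samples, shorter gaps interpolated),
step-sorted splitting, response curves, peak gains and tapping-error
differences. On synthetic data the pipeline recovers the generative 100 ms
latency to within one display frame and reproduces the error pattern —
no correction for steps within the latency of the tap (difference ≈ twice
the step size), a small overshoot for steps with ~50–100 ms of available
response time, and near-complete correction earlier. Passing these tests
shows the pipeline is internally consistent with the generators; it cannot
show that the generators capture real finger kinematics (muscle dynamics,
endpoint variability structure, or the movement-time adjustments to step
size are not modelled).

## Numerical and design choices

* The velocity estimate updates once per displayed frame, including frames
  during the reaction time; the estimate used for the error is the one
  available one delay (12 frames) before the tap, and the estimate at the
  tap is carried to the next trial. If a simulated tap occurs within one
  delay of onset the carried estimate is used and the trial flagged.
* First-trial estimates: the scheme mean (600 mm/s) for drifting sessions,
  0 for the acceleration sessions (directions alternate), and the mean
  signed initial speed for the all-rightward alternating scenario.
* Update order in learning follows the recursions exactly (retention
  multiplies the previous value, then the error term is subtracted), both
  corrections update after every trial in every block type, and the
  temporal correction modifies only the extrapolation horizon, not the
  simulated tap time.
* `timing_error` inverts the closed-form kinematics where available
  (choosing the earliest crossing before the velocity reverses) and
  otherwise searches the piecewise-linear path; when a decelerating target
  stops short of the tapped position the time of closest approach is
  returned and flagged (`undefined_crossing`) rather than silently used.
* Reported acceleration-session errors use the reference-block mean, the
  quantity the headline model predictions are quoted against; the all-trial
  mean is also computed and differs by under 0.15 mm.
* Seeding: every session derives one integer seed per trial
  (`derive_seed`), so any single trial can be regenerated in isolation;
  all seeds stay below 2³¹.
* Problem sizes: simulation-based quantities use 100–200 simulated
  sessions (standard errors well under the tolerances involved); the
  step-sorted plateau uses 10⁵ random walks; the pipeline checks use 1500
  synthetic trials.

## Known limitations

* The per-trial duration model is a normal stand-in; empirical duration
  distributions are right-skewed, and the slow-accumulation
  acceleration-session error inherits that uncertainty (see above).
* The synthetic finger data are a superposition of linear responses plus
  white noise — adequate for validating the analysis pipeline, not a
  biomechanical simulation.
* The initial-speed designs show the same qualitative overprediction as
  reported for the model: the simulated fast-vs-slow first-100 ms effect
  (≈4.2 mm) exceeds the ~3 mm observed in humans; the package implements
  the model as printed and reports, not resolves, this discrepancy.
* Learning of the update weight itself, Bayesian/Kalman weighting of
  prediction versus sensation, and movement-time adjustments to step size
  are out of scope.
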