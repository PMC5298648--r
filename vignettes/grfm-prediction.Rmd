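---
title: "Predicting ground reaction forces and moments from segment kinematics"
author: "gaitwrench"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting ground reaction forces and moments from segment kinematics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitwrench)
```

## The problem

Ground reaction forces and moments (GRF&M) are the mechanical interface
between the walking body and the ground, and the input of choice for joint
kinetics estimation. They are conventionally measured with laboratory force
plates, which confine the measurement to a few instrumented steps. When a
full-body motion capture system (optical or inertial) records the
kinematics of every body segment, the GRF&M can instead be *predicted*:
with ground contact as the only significant external load, Newton's and
Euler's equations of motion summed over all segments give the total
external wrench, and a distribution rule splits it between the feet.

`gaitwrench` implements this prediction pipeline end to end for level
walking, together with the evaluation metrics used to judge such
predictions, and a synthetic-gait generator with exactly known ground
truth so that every stage is testable without recorded data.

## Model

**Body model.** The body is a chain of 16 rigid segments. Per-segment mass
fractions, longitudinal centre-of-mass positions and radii of gyration are
the adjusted Zatsiorsky–Seluyanov values reported by De Leva (1996),
shipped verbatim as package data (`deleva_table()`). Scaling to a subject
(`scale_body()`) first subtracts the worn instrumentation mass (by default
a 17-IMU suit: 17 × 10 g plus a 150 g pack and a 70 g battery, 390 g in
total) from the measured mass, distributes the net mass by the tabulated
fractions, then adds each instrumentation component back onto its carrier
segment. The resulting segment mass enters the inertia tensor
$J_{kk} = m (r_k \ell)^2$; the instrumentation is assumed not to change the
radii of gyration $r_k$.

**Total external wrench.** With segment masses $m_i$, CoM accelerations
$a_i$, angular velocities $\omega_i$ and accelerations $\dot\omega_i$,
orientations $R_i$ and local inertia tensors $J_i$:

$$F_\mathrm{ext} = \sum_i m_i (a_i - g), \qquad
  M_\mathrm{ext}(O) = \sum_i \Big[ R_i J_i R_i^\top \dot\omega_i +
  \omega_i \times (R_i J_i R_i^\top \omega_i) +
  (c_i - O) \times m_i (a_i - g) \Big].$$

The per-joint internal forces that appear in a segment-by-segment Euler
balance cancel pairwise over the closed chain, so the whole-body moment
needs only the gravito-inertial term about the chosen reference point $O$.
Motion-capture exports express linear acceleration at the segment origin;
`translate_acceleration_to_com()` applies the rigid-body transfer
$a = a_o + \dot\omega \times r + \omega \times (\omega \times r)$.

**Frames.** Input kinematics live in the capture system's global frame
(vertical up). Outputs are reported in a walking frame sharing the
vertical, with the anterior axis along the pelvis displacement from the
first to the last sample (`walking_frame()`); the two differ by a pure
yaw.

**Gait events.** A per-foot two-state machine (`detect_events()`) declares
heel strike at the first sample where the heel point speed drops below
$0.6\,v_{th}$ and toe-off at the first sample where the toe speed exceeds
$1.9\,v_{th}$, with $v_{th}$ the norm of the trial-average pelvis velocity
(`compute_vth()`). Event times are whole sample times; a 50 ms minimum
inter-event gap suppresses chatter near the thresholds on noisy input.

**Double-support distribution.** During single support the grounded foot
carries the entire wrench, reported about the ground projection of its
ankle, recomputed each sample. Double support is statically indeterminate;
the package resolves it with a smooth transition assumption (STA): six
shape curves $f(\tau)$ on normalized double-support time
$\tau \in [0, 1]$ scale the trailing foot's wrench down from its value at
the contralateral heel strike ($f(0) = 1$) to zero at its own toe-off
($f(1) = 0$); the leading foot receives the remainder
(`distribute_wrench()`). Moments are scaled about the trailing ankle
projection at the heel strike and the remainder is transferred to the
leading ankle projection, so the sum of the two reported wrenches always
re-composes the total exactly — conservation holds at machine precision
by construction, whatever the curves.

**Curve sets are data.** The default curve set (`sta_default()`) is a
raised-cosine smooth step $(1 + \cos \pi\tau)/2$ for all six components:
the simplest C¹ shape satisfying both endpoint conditions with zero end
slope. Published transition curves for specific cohorts are not shipped
because no complete numerical tabulation of them is available; instead,
`calibrate_sta()` re-creates a cohort-specific set from any force-plate
corpus by normalizing each trailing-foot episode by its heel-strike value,
resampling to $\tau$, averaging, clamping the endpoints and fitting a
natural cubic spline — the same representation (knots + spline) the
default uses, so calibrated and default sets are interchangeable.

**Per-foot outputs.** With the wrench about the ankle ground projection in
the walking frame, the centre of pressure is $COP_x = -M_y / F_z$,
$COP_y = M_x / F_z$ (masked where $F_z \le 5$ N), and the frictional
torque is $T_F = M_z - COP_x F_y + COP_y F_x$. For reporting, forces are
normalized to body weight (BW), moments to body weight × body height
(BW·BH), and curves are resampled to 101 points per gait cycle (0–100%,
the conventional grid).

## Tunable parameters

| Parameter | Default | Units | Role |
|---|---|---|---|
| `cutoff_hz` | 6 | Hz | zero-phase Butterworth low-pass on $\omega$, $\dot\omega$, $a_o$ and point speeds |
| `filter_order` | 2 | – | order of one pass (applied forward and backward) |
| `heel_multiplier` | 0.6 | – | heel-strike threshold as a multiple of $v_{th}$ |
| `toe_multiplier` | 1.9 | – | toe-off threshold as a multiple of $v_{th}$ |
| `fz_threshold_N` | 5 | N | force-plate event detection and COP validity |
| `min_gap_s` | 0.05 | s | minimum inter-event gap per foot |
| `n_points` | 101 | – | percent-of-cycle resampling grid |
| `g` | 9.81 | m/s² | gravitational acceleration |

The filter is deliberately gentle: walking kinematics carry little power
above a few hertz, while numerical differentiation of angular velocity
(done *before* filtering, so the derivative is an input to the filter)
amplifies high-frequency noise. `run_sweep("cutoff", ...)` reproduces the
sensitivity analysis of this choice; on band-limited synthetic gait the
errors grow steeply below ~5 Hz and flatten above.

## The synthetic-gait generator

`generate_trial()` builds a 16-segment walking body from analytic curves
so that every derivative is exact and the ground truth is known to
machine precision:

* a base trajectory whose second derivative reproduces a prescribed total
  external force through Newton's equation run in reverse — vertical
  force oscillating around body weight at step frequency (amplitude
  0.12 BW), smaller anterior (0.15 BW, step frequency) and lateral
  (0.04 BW, stride frequency) components, phase-shifted so no component
  is zero at a heel strike;
* antiphase limb excursions (arms against legs, left against right) whose
  mass-weighted sum is identically zero, leaving the total wrench
  untouched while exercising the per-segment bookkeeping;
* heel/toe point speeds built from raised-cosine transitions that cross
  the detection thresholds exactly halfway between two samples, so the
  detected event lands on the prescribed sample;
* per-foot ground truth obtained by applying the same phase table and STA
  curves the predictor uses, coded independently;
* optional white Gaussian noise on the acceleration and angular-velocity
  channels, added after the truth is recorded.

The defaults emulate self-selected normal walking: 1.28 m/s, 1.2 s
strides, 12.5% double-support fraction, 240 Hz sampling, and a 77.34 kg,
1.81 m subject. Segments translate without rotating; the rotational Euler
terms are instead exercised by an analytic three-link pendulum oracle in
the test suite, where closed-form joint angles give a closed-form
reaction wrench. What the generator does **not** emulate: soft-tissue
artefact, orientation drift, magnetic disturbance, stance-foot rolling
contact, or inter-stride variability. Passing tests therefore demonstrate
algorithmic correctness — conservation, recovery of a known construction,
threshold behaviour — not field accuracy on real subjects, which requires
a force-plate comparison (`run_evaluate()`).

## Numerical choices

* **Zero-phase filtering** applies the designed second-order Butterworth
  forward and backward (squared magnitude, zero net phase). Both passes
  use odd-symmetric signal extension long enough (≥ 6 fs / cutoff
  samples) for the start-up transient to decay, making the DC gain
  exactly 1: constants pass through unchanged.
* **Differentiation** is by central differences (exact for linear
  signals), one-sided at the endpoints; it precedes filtering.
* **Event times** are whole sample times — no sub-sample interpolation —
  matching how event errors are conventionally reported.
* **$\tau$ normalization** uses the actual event-bounded interval of each
  double-support episode, not a nominal duration.
* **Moment bookkeeping**: the total moment is computed once about the
  global origin and re-expressed where needed with the exact wrench
  transfer `transfer_wrench()` (involutive, conserving the screw), which
  is what makes conservation hold to rounding error.
* **STA splines** are natural cubic splines through tabulated knots with
  endpoint values clamped to 1 and 0; evaluation outside $[0,1]$ is an
  error, and the endpoints are returned exactly.
* **Degenerate inputs**: zero-length double-support intervals, stationary
  trials (no walking direction), missing contact points and non-positive
  net mass are either rejected with named errors or degrade to a
  total-wrench-only result with a warning, as appropriate.

## Open design points, resolved

* Direction of the threshold inequalities: heel strike on the heel speed
  *falling* below its threshold, toe-off on the toe speed *rising* above
  its — the foot decelerates into contact and accelerates out of it.
* The initial machine state of each foot is inferred from its first
  heel-speed sample; the first (possibly truncated) phase of a trial is
  labelled accordingly.
* Trunk/pelvis CoM offsets are placed purely along the segment
  longitudinal axis, as the single tabulated CoM column implies.
* Evaluation correlations are computed per gait cycle and then averaged
  (the SD across cycles is reported), rather than pooling samples.
* Before averaging stance curves across feet, left-foot curves are
  mirrored (lateral force, frontal and transverse moments negated) so
  antisymmetric components do not cancel.

## Problem sizes used by the tests

The suite runs on 2–4-stride trials (≈1300–1700 samples at 240 Hz) for
pipeline checks, a 25-stride trial (52 double-support episodes) for STA
calibration recovery, and a 2 s pendulum simulation for the dynamics
oracle. These sizes were chosen as the smallest that exercise several full
gait cycles with stable averages.

## Limitations

* The STA applies to gait only, and only after the full double-support
  phase is observed — the method is not real-time during double support.
* Anthropometric tables are population averages; segment parameters for
  elderly, paediatric or obese subjects differ.
* The event detector is validated for normal walking-speed regimes;
  considerably slower or faster gait, stairs, or pathological patterns
  may defeat fixed threshold multipliers.
* Only ground contact is modelled: canes, handrails or carried loads
  violate the single-external-load assumption.

## A minimal run

```{r example}
trial <- generate_trial(synthetic_trial_spec(n_strides = 3))
pred <- run_predict(trial$kinematics, trial$body)
report <- run_evaluate(pred, trial$truth$left, trial$truth$right, trial$body)
report$per_component[, c("component", "rho", "category", "rrmse_percent")]
```
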