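---
title: "Trajectory-guided haptic training: models and design choices"
author: "arthroguide"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trajectory-guided haptic training: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(arthroguide)
```

## The problem

Arthroscopic inspection of the knee demands fine motor skill in a narrow,
poorly visible joint space. An effective way to transfer that skill is to
record an experienced surgeon's arthroscope trajectory with an optical
tracker, turn it into a smooth reference curve, and have novices practice
against it on a haptic device that gently pulls their stylus back toward
the reference path. `arthroguide` implements this pipeline end to end in
software: the tracking geometry, the curve model, the guidance force laws,
a simulated trainee in place of the physical device, and the skill metric
used to score sessions.

## Tracking geometry

A square fiducial of known side length is rigidly attached to the
arthroscope. Each camera with intrinsics $K$ observes the four marker
corners; the extrinsic $T_{cm}$ (marker frame $\to$ camera frame,
$P_c = R\,P_m + t$) is recovered from the four correspondences.

*Pose recovery.* The published description cites a standard marker-tracking
method without specifying its internals, so we use the textbook equivalent
for a known-size planar square: a direct-linear-transform homography from
the four corner correspondences, decomposed against $K$, with the rotation
re-orthonormalized by SVD and the sign fixed so the marker lies in front of
the camera. Noiseless synthetic projections are recovered to better than
$10^{-6}$ in both translation and rotation entries; under pixel noise the
translation error grows with depth, as expected for a fixed-size target.

*Corner convention.* The canonical corners are $(\pm s/2, \pm s/2, 0)$ in
the marker plane, counter-clockwise starting top-left. Only the convention
matters (it fixes the recovered orientation); any consistent choice works.

*Two cameras.* The second camera exists to survive occlusion. Both
camera-to-marker transforms determine the fixed stereo transform
$T_{rl} = T_{mr}^{-1} T_{ml}$ (left-camera coordinates to right-camera
coordinates). Frame resolution prefers the left camera; falls back to the
right camera, mapping its pose through $T_{rl}^{-1}$ into the left-camera
convention; and otherwise repeats the previous pose, marked
`source = "held"`. Held samples keep downstream fitting honest about
dropout without interpolating data that was never observed; they carry
equal weight in the fit by default. How $T_{rl}$ is calibrated in a
physical rig is out of scope: the rig configuration takes it as given.

All frames are right-handed; quaternions are stored w-first and kept on
the $q_w \ge 0$ hemisphere so serialized output is reproducible.

## The NURBS trajectory model

The recorded positions $Q_i$, $i = 0,\dots,n-1$, are parameterized by
normalized recording time $\bar u_i = (t_i - t_0)/(t_1 - t_0)$ and fit by
a degree-$p$ NURBS curve

$$C(u) = \frac{\sum_i N_{i,p}(u)\, w_i P_i}{\sum_j N_{j,p}(u)\, w_j},
\qquad u \in [0, 1],$$

on a clamped knot vector, with $m < n$ control points. The basis is the
Cox–de Boor recursion with $0/0$ terms taken as $0$ and the domain closed
at $u = 1$.

Design choices, in the order they matter:

* **Degree** defaults to cubic ($p = 3$), the standard choice for
  smooth trajectories with continuous curvature.
* **Weights** default to 1 and are treated as fixed inputs, never
  optimized; with unit weights the curve is an ordinary B-spline.
* **Pinned endpoints.** The first and last control points are set to the
  first and last data points, so the smoothed path starts and ends exactly
  where the recording did; the interior control points solve the linear
  least-squares problem $\min \sum_i \lVert C(\bar u_i) - Q_i\rVert^2$ by
  QR after substituting the pinned rows. One basis matrix serves all three
  coordinates.
* **Knot placement.** Interior knots are placed by the averaging rule
  applied to the data parameters resampled at $m$ positions (linear
  interpolation of $\bar u$). This keeps every basis function supported on
  data (Schoenberg–Whitney) and the normal equations well conditioned for
  strongly non-uniform pacing.
* **Orientation is not spline-fitted.** The curve models positions only;
  the recorded quaternions stay with the raw samples. Orientation
  smoothing is a deliberate non-goal.
* **Closest-point projection** (needed by the static force and the skill
  metric) uses a coarse scan over a 512-point cached parameter grid
  followed by refinement: Brent minimization (tolerance $10^{-10}$ in $u$)
  for the scalar interface, and a safeguarded Newton iteration on the
  squared-distance derivative — with analytic first and second curve
  derivatives — for the vectorized batch path. Ties break toward the
  smallest parameter. Both paths are cross-checked against a
  $10^5$-point dense scan in the tests.

Fitting both *filters* tracker noise (the fitted curve's total discrete
curvature is strictly below the raw polyline's on noisy input) and
*compresses* the recording (a 601-sample recording becomes 14 control
points; the serialized JSON is a fraction of the CSV).

## Guidance force laws

Three regimes, dispatched by a two-phase state machine
(initialization $\to$ tracking, never back):

1. **Attractive** (initialization): with offset $r = \lVert C(t_0) - D\rVert$
   from the probe $D$, the force is saturated at magnitude $k_A d_A$ for
   $r > d_A$, equals $k_A (C(t_0) - D)$ for $d_t \le r \le d_A$, and is
   zero inside the dead zone $r < d_t$. The two outer regimes meet
   continuously at $r = d_A$. As printed, the law *jumps* from magnitude
   $k_A d_t$ to zero at the dead-zone boundary; we implement that jump
   literally (fidelity first — it is the construction's own choice) and
   expose `smooth_dead_zone` to ramp it linearly to zero for users who
   want a continuous field.
2. **Static** (tracking, default mode): $F = k_s\,(C(u^*) - D)$ along the
   contour error to the closest curve point — normal to the curve tangent
   at interior minimizers — imposing geometry but no pacing.
3. **Time-dependent** (tracking): $F = k_d\,(C(u(t_t)) - D)$ toward the
   time-scheduled target, reproducing the expert's pacing as well; the
   target replays the recorded clock at a configurable `playback_rate`
   (default 1), started when tracking begins. Which mode the original
   evaluation used is not stated; both are exposed and static is the
   default.

Every force is finally scaled by $(1 - v)$ with the training strength
$v \in [0, 1]$: full guidance at $v = 0$, none at $v = 1$ — linearity that
the tests check in every regime.

No published numeric values exist for $k_A, k_s, k_d, d_A, d_t$; the
defaults (stiffness 5 force/cm, $d_A = 1$ cm, $d_t = 0.1$ cm) are package
configuration values in device-normalized units, not measured constants.

## The synthetic-data engine

The generator stands in for three physical things and is first-class,
tested code:

* **Expert path**: a cardinal cubic (Hermite) spline through uniform
  random waypoints drawn in the inner 75% of a 10 cm workspace box
  (margin against spline overshoot), sampled at 30 Hz — the capture rate
  of the original rig — over a 20 s default recording. The `smoothness`
  parameter scales the Catmull–Rom tangents.
* **Tracker noise**: i.i.d. Gaussian position noise (default 0.05 cm SD
  per axis) plus per-frame dropout (default 2%) that repeats the previous
  emitted pose, exactly as the tracking chain's hold-last-pose rule does.
* **Trainee**: a damped point mass (mass 0.1, damping 3, intent gain 20
  force/cm) pulled toward a target advancing along the curve, with
  Gaussian intent noise (`skill_sigma`, default 0.3 cm) re-drawn every
  frame. The feedforward terms are matched to the discrete semi-implicit
  Euler update so that exact tracking of the advancing target is a fixed
  point of the integrator: a noise-free operator without guidance follows
  the curve to ~0.001 cm, so measured errors reflect operator noise and
  guidance, not integration artifacts. Integration runs at the 30 Hz
  tracker rate — this is a desk-scale simulation, not device firmware.

Parameters were chosen once as desk-scale values giving stable integration
and unguided errors of a few millimetres — the same order as recorded
novice performance — and are clearly synthetic: they are not estimates of
any human subject's dynamics, and the simulator deliberately omits
biomechanics, tremor spectra, within-session learning, and soft-tissue
interaction. Passing tests therefore show that the *pipeline* behaves as
specified (guidance helps a noisy operator, stiffer springs help more),
not that any particular human cohort would reproduce the packaged
percentages.

Sessions derive one RNG stream per virtual subject from
`(master_seed, subject_id)`, so cohorts are reproducible subject-by-subject
and guided/unguided arms can be paired on identical noise streams.

## Skill metric and cohort statistics

The **normal path error** of a trainee sample is its shortest distance to
the expert curve; a session reports the per-sample errors, their mean
(AVG, cm), sample standard deviation (SD, $n-1$ convention — the published
tables do not state a convention, and packaged table cells are fixture
data, never recomputed), and the operation time in seconds.

The packaged eight-subject cohort tables (guided and unguided conditions,
first and second sessions) ship as plain CSV fixtures. The headline
comparison is the mean over subjects of the per-subject relative reduction
$1 - \text{with}/\text{without}$ on the *second-session* rows — the unique
aggregation consistent with both published percentages, which the test
suite verifies to two decimals (33.01% for mean error, 14.95% for
operation time):

```{r cohort}
w0 <- read_cohort_csv(arthroguide_fixture("cohort_without_guidance.csv"))
w1 <- read_cohort_csv(arthroguide_fixture("cohort_with_guidance.csv"))
cohort_comparison(w0, w1)
```

## Numerical choices and degenerate inputs

* Basis evaluation is vectorized over parameters; partition of unity holds
  to $10^{-12}$ on a 1001-point grid, and evaluation agrees with an
  independent spline implementation to $10^{-10}$.
* `fit` requires $p + 1 \le m < n$; $m \ge n$ is rejected as "no
  compression", rank-deficient bases as ill-conditioned.
* A zero-length time window, decreasing timestamps, non-positive weights,
  non-unit quaternions beyond $10^{-6}$ (renormalized with a warning) and
  degenerate (collinear) marker corners all fail loudly.
* Curve JSON is written with 17 significant digits so serialization
  round-trips doubles exactly.
* The simulation aborts with the offending step if its state ever becomes
  non-finite.

## Problem sizes

The test suite and the reproduction script run everything at the scale the
method actually operates at: recordings of 10–20 s at 30 Hz (300–600
samples), curves with 10–14 control points, cohorts of 8 virtual subjects,
and 100-pose batches for the tracking-chain checks. A full reproduction
run completes in well under a minute on one core.

## Known limitations

* Real-image marker segmentation, lens-distortion calibration, rendering,
  and physical haptic I/O are out of scope; intrinsics and the stereo
  transform are taken as given.
* The trainee model is a deliberately simple controlled point mass; it
  demonstrates the guidance mechanism, not human motor learning.
* Orientation error is not part of the skill metric (positions only),
  matching the published metric.
* Multi-pass recordings are not stitched; one curve models one inspection
  pass.
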