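---
title: "Breaststroke kinematics from inertial sensors: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Breaststroke kinematics from inertial sensors: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swimkin)
```

`swimkin` estimates lower-limb joint kinematics during breaststroke
swimming from eight body-worn 6-axis inertial sensors, derives a
spatiotemporal and coordination parameter set per trial, and supports
group statistics and movement phenotyping. This vignette explains the
models behind each stage, the parameters that matter, the numerical
choices, and what the synthetic validation does and does not establish.

## Orientation estimation

Each sensor's orientation quaternion $q_{ES}(t)$ (sensor frame $S$ to
Earth frame $E$, Hamilton convention, scalar first) is estimated by a
gradient-descent complementary filter. Per sample the body-frame
angular-rate increment is applied exactly through the quaternion
exponential, $q \leftarrow q \otimes \exp(\tfrac{1}{2}\,\omega\,\Delta
t)$, and then a normalized gradient step of size $\beta\,\Delta t$ pulls
the predicted gravity direction toward the measured accelerometer
direction. Using the exponential map (rather than a first-order
quaternion-rate step) means the filter at $\beta = 0$ *is* gyro-only
quaternion-exponential integration, to machine precision — a useful
exact limit for testing. Timestamps are taken per sample, so irregular
sampling is handled without assuming $1/f_s$.

Accelerometers measure gravity only when the sensor is not
accelerating. During the propulsion snap the feet see several m/s² of
motion acceleration, and letting those samples steer the gravity
reference biases the attitude. The correction is therefore *gated*:
samples with $|\,\lVert a \rVert - g\,| >$ `accel_gate` (default
0.3 m/s²) receive a gyro-only update, and the reference is re-acquired
during the quieter glide. A zero-norm accelerometer sample likewise
falls back to a gyro-only update rather than erroring mid-stream.

Tunable parameters:

| parameter | default | units | rationale |
|---|---|---|---|
| `beta` (movement) | 0.1 | rad/s | standard gain for this filter class: slow enough not to chase motion acceleration, fast enough to bound gyro drift |
| `beta_static` | 2.0 | rad/s | fast convergence inside the known-static calibration window |
| `accel_gate` | 0.3 | m/s² | keeps ~95 % of resting samples under the default accel noise (σ = 0.15 m/s²) while rejecting kick transients |
| `gyro_rms_max` | 0.1 | rad/s | motion guard for the static window; well above typical bias (σ = 0.005 rad/s), well below any deliberate movement |

There is no magnetometer term: magnetometer data are unusable in a pool
environment, so absolute yaw is unobservable and handled structurally
(next section).

## Frame alignment and sensor-to-segment calibration

The protocol starts with ~15 s of motionless standing. Three things are
extracted from that window:

1. **Initial attitude** per sensor — roll/pitch from the mean
   accelerometer direction, yaw set to zero.
2. **Common Earth frame** — every sensor's heading (rotation about the
   vertical) is rotated so that its y-axis points "forward" at stance,
   which simultaneously matches all headings to the reference
   right-thigh sensor and anchors the analysis convention (x down,
   y forward, z right by the right-hand rule). Since absolute yaw is
   unobservable, "forward" is *defined* by the calibration stance; a
   common heading error relative to the true swim direction only enters
   the sagittal angles at second order.
3. **Sensor-to-segment offsets** — the mean sensor orientation over the
   window. Joints are assumed neutral (0°) when standing, so the
   segment orientation is $R_{EB}(t) = R_{ES}(t)\,R_{ES}(t_0)^{\top}$:
   any constant mounting rotation and any body-curvature inclination is
   absorbed, and all joint angles average 0° over the window by
   construction.

Joint angles come from the relative rotation $R_{S_1S_2}(t) =
R_{ES_1}(t)^{\top} R_{ES_2}(t)$ between the calibrated proximal and
distal segment frames (hip: lower back → thigh; knee: thigh → shank;
ankle: shank → foot; the upper-back sensor is ingested but unused in
joint math). The decomposition is intrinsic Z–Y–X, chosen because
flexion/extension is the dominant rotation in breaststroke and should
be extracted first: the z-angle is flexion/extension
(dorsi/plantarflexion at the ankle), the y-angle hip
abduction/adduction. Knee and ankle flexion rotate the distal segment
backward about the mediolateral axis, so their z-angle carries a
negative anatomical sign and flexion is reported positive, with full
knee extension at 0°. Angles are unwrapped; samples with the middle
Euler angle within 1° of ±90° are flagged as gimbal-proximal and
linearly interpolated over (breaststroke never approaches this in the
sagittal plane).

**Identifiability limit.** With 6-axis sensors and a static pose, the
*yaw* component of a mounting rotation cannot be separated from the
unobservable heading: inclination offsets (what straps and body
curvature actually produce, and what the static pose is meant to
correct) cancel exactly, while a mounting yaw of $\epsilon$ leaks into
flexion only at second order ($\approx \epsilon^2/2$ at high flexion)
but into abduction/adduction at first order. Sagittal-plane angles are
therefore the primary outputs, mirroring how such sensor set-ups are
used in practice.

## Stroke segmentation

Cycle starts are maxima of knee extension: local minima of the sagittal
knee angle with topographic prominence ≥ `min_prominence` (default 10°,
rejecting tremor and noise dips) and spacing ≥ `min_period` (default
1 s, below any plausible breaststroke rate). Detection runs on a
zero-lag 4th-order Butterworth low-pass at 6 Hz (`signal::filtfilt`);
stroke content lies below ~1 Hz, so this suppresses sensor noise
without moving event times. The first and last partial cycles have no
enclosing minima and are discarded by construction. Cycles are
half-open intervals $[e_k, e_{k+1})$ — no sample belongs to two cycles —
and each is linearly interpolated onto 100 uniform cycle-percentage
points (linear, not spline: monotone, no overshoot at the sharp
propulsion peak; endpoints preserved exactly). Fewer than two detected
events is an explicit "no strokes detected" error, and cycles with
fewer than four samples are dropped with a warning.

## The parameter set

All per-stroke parameters are means over all strokes; SDs across
strokes are kept for stroke duration, ACC and phase shift as
variability measures.

* **Temporal.** Durations are event-to-event times, pooled across legs;
  stroke rate is $60/\bar d$. Velocity is total configured distance
  over active time — the configured lap boundary times when available
  (the timed push-off/wall-touch of a real lap), else the event-bounded
  range; the boundary-time route is preferred because the detector
  deliberately discards the first and last partial cycles. Distance per
  stroke is velocity × mean duration. Without lap metadata, velocity
  and distance per stroke are reported `NA` and everything else is
  still computed.
* **RoM and extrema.** Per-cycle max − min on the 100-point cycles,
  averaged; extrema are means of per-cycle minima and maxima.
* **Cyclograms.** Ankle–knee and knee–hip sagittal angle–angle curves
  per cycle. SSD between two *centered* cyclograms is
  $\sum_{i=1}^{100} \lVert c^{(1)}_i - c^{(2)}_i \rVert^2$ (deg²);
  a subject's SSD is measured from their mean cyclogram to the healthy
  reference shape, and the asymmetry SSD between the two legs' mean
  cyclograms. Passing an uncentered cyclogram to SSD is an error, not a
  silent centering.
* **ACC.** For each of the 99 segment transitions, the frame-to-frame
  direction $\theta_{k,i} = \operatorname{atan2}(\Delta y, \Delta x)$
  per cycle $k$; the mean resultant length across cycles measures
  directional agreement at $i$, and ACC is the mean over $i$. Exact
  replicates give ACC = 1; uniformly random directions give ACC → 0.
  Zero-length segments are excluded from their point's mean. The
  reported ACC "SD" is the spread of the pointwise consistencies across
  the cycle — a within-cycle variability profile, since ACC itself is
  already an across-cycle statistic.
* **Phase shift.** For each left event, the signed offset to the
  nearest right event divided by the current left stroke duration,
  wrapped to ±50 % (a shift cannot exceed half a cycle); the mean of
  absolute values is reported, with their SD as variability. 0 % =
  synchronized legs.
* **Asymmetry.** $100\,|RoM_L - RoM_R| / \overline{RoM}$ per joint
  (0 when both are zero), computed on RoM — the natural per-joint
  scalar — rather than on pointwise angles.
* **Ankle displacement.** Shank-sensor acceleration rotated to the
  Earth frame, gravity subtracted, double-integrated inside each
  propulsion window — peak knee flexion to the next maximum extension,
  when the legs extend and generate thrust — with a linear velocity
  de-drift pinning velocity to zero at both window ends (the limb is
  momentarily quasi-stationary at peak flexion and in the glide).
  Windows shorter than 0.2 s are skipped. Axes: vertical = gravity (x),
  horizontal = swim direction (y), lateral = z.
* **Profiles.** $Z = (x - \mu)/\sigma$ per parameter against a healthy
  reference; a zero reference SD is an error naming the parameter.

## Statistics and phenotyping

Group comparisons use `stats::kruskal.test` (tie-corrected H) with
$\varepsilon^2 = H(n+1)/(n^2-1) = H/(n-1)$, Holm–Bonferroni adjustment
(`p.adjust`), Mann–Whitney U (`wilcox.test`; $U$ counts pairs where the
first sample exceeds the second, ties half; rank-biserial
$r = 2U/(n_1 n_2) - 1$, +1 for complete dominance of the first sample)
and Fisher's exact test (`fisher.test`; a zero-margin table returns
p = 1). An optional rank-on-rank covariate adjustment (residuals of
`lm(rank(y) ~ rank(covariates))`) is available for age/BMI-style
controls and is off by default.

Phenotyping standardizes the parameter matrix, keeps the smallest
number of principal components reaching 70 % cumulative explained
variance (configurable; constant columns are dropped with a warning),
and runs k-means with k-means++ seeding and 50 restarts per candidate
k. Model order is chosen by the elbow criterion — the maximum second
difference of the within-cluster sum of squares, including the k = 1
total — with ties broken toward smaller k; mean silhouette widths
(`cluster::silhouette`) and the gap statistic (uniform reference over
the data's bounding box, B = 50 sets, seed-fixed) are reported
alongside so the choice can be overridden. Discriminative features are
the top-5 |loading| parameters per retained component, deduplicated,
Kruskal–Wallis-tested across clusters with Holm correction at α = 0.05,
with pairwise Mann–Whitney post hocs.

One caveat is deliberate: testing for parameter differences between
clusters *found by k-means on the same data* is circular, and no
false-positive guarantee exists on that path. The package's type-I
control property is therefore established against label-randomized
assignments on single-phenotype cohorts, where the α-level claim is
well-defined.

## What the synthetic generator emulates — and what it does not

The generator builds per-joint cycle waveforms from smooth raised-cosine
bumps peaking mid-cycle (knee 90°, hip 40°, hip abduction 18°, ankle
28° by default), with a small knee flexion (4°) held through the glide
so that maximum extension is a sharp, detectable event at the cycle
boundary rather than a flat plateau — real knees are never perfectly
still in water. Strokes get durations with a configurable CV, the right
leg a configurable phase lag (with per-stroke jitter), per-leg/per-joint
amplitude scales (impairments), and per-cycle amplitude noise. Segment
orientations follow the pelvis → thigh → shank → foot chain with
anthropometric segment lengths (thigh 0.42 m, shank 0.43 m, foot
0.20 m); gyro signals are the exact body-frame angular increments plus
a per-sensor constant bias (σ = 0.005 rad/s) and white noise
(σ = 0.01 rad/s); accelerometers see gravity in the sensor frame plus
the chain's linear acceleration plus white noise (σ = 0.15 m/s²);
mounting offsets are random constant rotations (σ = 10°). Every stream
is reproducible from (specification, seed), and no synthetic stream is
used in a test without its truth record.

Not emulated: hydrodynamic drag and buoyancy forces, soft-tissue
artifact, trunk and arm kinematics (the study design suppresses arm
motion with a kickboard), sensor dropouts, and temperature-dependent
bias drift. Passing the synthetic validation therefore shows the
*algorithmic* chain is correct under realistic noise, bias and mounting
conditions; it does not certify accuracy against optical motion capture
on real swimmers, which requires instrumented trials.

The cohort generator draws per-subject templates from phenotype
distributions (an unimpaired "healthy" phenotype; a mildly impaired,
low-variability phenotype; a strongly impaired phenotype with distal
RoM deficits, high timing variability and pronounced asymmetry —
deficit directions following the clinical pattern of impaired
breaststroke) and computes subject parameters from the ground-truth
kinematics directly. This keeps hundreds-of-subjects experiments cheap;
the IMU round-trip is validated separately end to end.

## Numerical choices and degenerate inputs

* Quaternions are re-normalized after every update; emitted norms are
  within 1e-9 of unity. Matrix → quaternion conversion uses Shepperd's
  pivoting; signs are fixed scalar-nonnegative.
* Static-window orientation averaging uses the sign-fixed chordal mean,
  adequate for tightly clustered rotations.
* Quaternion log/exp round-trips hold below the π principal branch;
  rotations are kept there by construction.
* Event detection prominence is the standard topographic definition,
  computed exactly (O(n · peaks)); of two events closer than
  `min_period`, the deeper minimum wins.
* Integration uses trapezoids; de-drifting is a linear velocity ramp.
* Degenerate statistics: all-identical samples give H = 0, ε² = 0,
  p = 1; empty groups, non-overlapping event series, missing sensors,
  unmapped sensor IDs, absent unit headers, and data gaps > 2/rate are
  explicit, named errors.
* All randomness (noise draws, k-means restarts, gap references) hangs
  off a single seed; identical inputs and seed give byte-identical
  outputs.

## Validation problem sizes

The shipped tests validate: filter limits against closed-form and
exponential-integration oracles (1e-6); tilt tracking under noise over
60 s (< 2° RMSE); calibration invariance to inclination-dominant
mounting offsets (< 0.5°); a full noisy 15-stroke pipeline round trip
(knee/hip RMSE well under the 5° acceptance bound, typically ~1–1.5°);
ACC/SSD/phase-shift algebra against brute-force oracles (1e-12); rank
statistics against enumeration oracles on ≤ 8-element inputs; recovery
of injected RoM (±2°), phase lag (±1 %), duration CV (±0.02) and
velocity (±5 %) on a 40-stroke trial; two-phenotype cohorts of 30
subjects recovered with ARI ≥ 0.9; and a 200-replicate null-cohort
check that discriminative features appear at most at rate α plus
Monte-Carlo error. These sizes were chosen as the smallest that make
each property statistically meaningful.

## Known limitations

* Absolute heading is undefined; all horizontal directions are relative
  to the calibration stance.
* Mounting yaw is unidentifiable from a static pose (second-order in
  flexion, first-order in abduction/adduction); frontal-plane hip
  angles should be read with that in mind.
* Relative yaw drifts slowly between sensors over a trial (gyro bias
  about the vertical is uncorrected); trials are assumed ≤ ~90 s.
* The ankle-displacement de-drift assumes near-zero limb velocity at
  the propulsion window ends; vigorous non-stereotyped movements
  violate it.
* Velocity requires lap metadata; the toolkit does not integrate
  displacement over minutes-long spans.
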