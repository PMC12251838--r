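# swimkin

Lower-limb breaststroke kinematics from body-worn inertial sensors.

Clinical movement analysis of swimming — for example in people with
incomplete spinal cord injury, where water offloads body weight and makes
leg movements possible that gait tests cannot elicit — needs a way to
measure joint kinematics without cameras. `swimkin` turns raw 200 Hz
gyroscope/accelerometer streams from eight waterproof IMUs (left/right
thigh, shank, foot; upper and lower back) into joint angles, stroke
cycles, and a full set of spatiotemporal and coordination parameters,
and provides the statistics and clustering used to compare groups and
discover movement phenotypes.

## Method in brief

* **Orientation.** Each sensor's orientation quaternion q_ES(t) is
  estimated with a gradient-descent complementary filter (Madgwick
  class): exact quaternion-exponential gyro integration, corrected
  toward the accelerometer gravity direction with gain β (0.1 during
  movement, 2.0 during the 15 s standing calibration), with the
  correction gated off when ‖a‖ deviates from 1 g. 6-axis only — no
  magnetometer, which is unusable in a pool.
* **Calibration.** All sensors are aligned to a common Earth frame
  (x down, y forward, z right; right-thigh sensor as heading reference)
  and a static standing pose removes sensor-to-segment mounting
  offsets, so every joint reads 0° when standing.
* **Joint angles.** Relative segment rotation R_S1S2(t) = R_ES1(t)ᵀ ·
  R_ES2(t), decomposed as intrinsic Z–Y–X Euler angles: z → flexion/
  extension (knee, ankle, hip), y → hip abduction/adduction. Full knee
  extension = 0°, flexion positive.
* **Cycles.** Stroke cycles start at maximum knee extension (minima of
  the sagittal knee angle), and each cycle is resampled to 100 points.
* **Parameters.** Velocity, stroke rate, stroke duration (mean, SD),
  distance per stroke, joint extrema and range of motion (RoM), ankle
  displacement during propulsion, angle–angle cyclograms with their
  shape deviation SSD = Σᵢ‖c1ᵢ − c2ᵢ‖² against a healthy reference,
  the angular component of the coefficient of correspondence
  (ACC ∈ [0, 1], a circular statistic of cyclogram repeatability),
  left–right asymmetry, asymmetry SSD, and inter-limb phase shift
  (% of cycle; 0 % = synchronized legs). Profiles are z-scored against
  a healthy cohort: Z = (x − μ)/σ.
* **Statistics & phenotyping.** Kruskal–Wallis tests with ε² = H/(n−1)
  effect sizes and Holm–Bonferroni correction, Mann–Whitney U with
  rank-biserial r, Fisher's exact test; PCA to a cumulative
  explained-variance target, then k-means (k-means++ seeding) with
  elbow / silhouette / gap-statistic diagnostics and discriminative-
  feature extraction.
* **Synthetic ground truth.** A breaststroke generator (glide →
  recovery → propulsion waveforms, kinematic chain, gravity + motion
  accelerations, gyro noise and bias, mounting offsets, configurable
  impairments) provides exact truth for validating the whole pipeline.

## Worked example

```r
library(swimkin)

# one synthetic swimmer: 10 strokes, 7 % inter-leg lag, mild variability
template <- breaststroke_template(duration_cv = 0.05, cycle_jitter = 2,
                                  phase_lag = 7)
kin <- generate_kinematics(template, n_strokes = 10, seed = 42)
sim <- kinematics_to_imu(kin, seed = 42)    # noisy 200 Hz IMU streams

config <- default_config()
config$static_window <- c(0.3, 2.7)
config$lap_length <- kin$lap$lap_length
config$n_laps <- kin$lap$n_laps
config$lap_boundaries <- c(kin$lap$t_start, kin$lap$t_end)

trial <- analyze_trial(sim$streams, config,
                       reference = reference_cyclograms())
round(trial$params[c("velocity", "stroke_rate", "stroke_duration_mean",
                     "rom_knee_L", "rom_knee_R", "acc_ankle_knee_L",
                     "phase_shift_mean", "asym_knee")], 3)
#>             velocity          stroke_rate stroke_duration_mean
#>                0.400               29.237                2.052
#>           rom_knee_L           rom_knee_R     acc_ankle_knee_L
#>               94.871               96.461                0.936
#>     phase_shift_mean            asym_knee
#>                6.241                1.662
```

The swimmer covered 0.40 m/s (the generator's configured velocity,
recovered from lap metadata), took ~29 strokes/min of ~2.05 s each, the
knee moved through ~95° per stroke on both legs (truth 93.7°), the
ankle–knee cyclograms repeat with ACC 0.94, the injected 7 % phase lag
is recovered as 6.2 %, and the legs are nearly symmetric (1.7 % knee
asymmetry).

A command-line interface wraps the same functions:

```sh
Rscript inst/cli/swimkin simulate --out demo --seed 11 --n-strokes 5
Rscript inst/cli/swimkin params --in demo --config demo/config.yaml --out demo/params
```

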