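#' Synthetic breaststroke generator
#'
#' Ground-truth test bed: quasi-periodic breaststroke joint-angle
#' trajectories (glide, recovery, propulsion), segment orientations
#' consistent with them, and forward-simulated gyro/accel streams with
#' configurable noise, biases, mounting offsets and impairments (reduced
#' range of motion, inter-leg phase lag, stroke-duration variability,
#' left-right asymmetry).
#'
#' @name synthgen
NULL

# smooth periodic raised-cosine bump on cycle phase p in [0, 1):
# 0 outside [center - width/2, center + width/2] (mod 1), peak 1 at center
raised_cosine <- function(p, center, width) {
  d <- (p - center + 0.5) %% 1 - 0.5
  out <- numeric(length(p))
  inside <- abs(d) < width / 2
  out[inside] <- 0.5 * (1 + cos(2 * pi * d[inside] / width))
  out
}

# knee waveform detail: the glide is not perfectly still -- the knee
# reaches its extension peak at the end of the propulsion snap (the cycle
# boundary) and sits a few degrees flexed through the glide. Modeled as a
# narrow notch to zero at the boundary; without it the cycle-start
# minimum would be a flat plateau, which no detector (and no swimmer)
# produces.
glide_notch <- function(p, amp, width) {
  amp * (1 - raised_cosine(p, 0, width))
}

#' Breaststroke kinematic template
#'
#' Per-joint cycle waveforms built from smooth raised-cosine bumps, zero
#' (neutral) at the cycle boundary (the glide, maximum knee extension)
#' and peaking mid-cycle where flexion is greatest. Default peak
#' amplitudes: knee 90, hip 40, hip abduction 18, ankle 28 degrees --
#' typical able-bodied breaststroke kick magnitudes.
#'
#' @param stroke_duration mean stroke duration, s (default 2).
#' @param rom_scale named list of per-leg amplitude scale factors, e.g.
#'   `list(L = c(knee = 1, hip = 1, hip_abd = 1, ankle = 1), R = ...)`;
#'   a single unnamed number scales everything.
#' @param phase_lag right-vs-left cycle lag, % of cycle (default 0).
#' @param phase_lag_jitter per-stroke SD of the lag, % (default 0).
#' @param duration_cv coefficient of variation of stroke durations
#'   (default 0).
#' @param cycle_jitter per-cycle amplitude shape noise, degrees SD
#'   (default 0).
#' @param glide_flexion small knee flexion held through the glide,
#'   degrees (default 4): the knee only touches full extension at the
#'   end of the propulsion snap, so the cycle-start minimum is a sharp,
#'   detectable extension peak rather than a flat plateau.
#' @return list of class `kin_template`.
#' @export
breaststroke_template <- function(stroke_duration = 2,
                                  rom_scale = 1,
                                  phase_lag = 0,
                                  phase_lag_jitter = 0,
                                  duration_cv = 0,
                                  cycle_jitter = 0,
                                  glide_flexion = 4) {
  stopifnot(stroke_duration > 0, duration_cv >= 0, cycle_jitter >= 0,
            phase_lag >= -50, phase_lag <= 50, glide_flexion >= 0)
  base <- list(
    knee    = list(amp = 90, center = 0.50, width = 0.60),
    hip     = list(amp = 40, center = 0.50, width = 0.70),
    hip_abd = list(amp = 18, center = 0.55, width = 0.50),
    ankle   = list(amp = 28, center = 0.55, width = 0.50))
  if (is.numeric(rom_scale) && length(rom_scale) == 1) {
    rom_scale <- list(L = stats::setNames(rep(rom_scale, 4), names(base)),
                      R = stats::setNames(rep(rom_scale, 4), names(base)))
  }
  stopifnot(all(unlist(rom_scale) >= 0))
  structure(list(base = base, stroke_duration = stroke_duration,
                 rom_scale = rom_scale, phase_lag = phase_lag,
                 phase_lag_jitter = phase_lag_jitter,
                 duration_cv = duration_cv, cycle_jitter = cycle_jitter,
                 glide_flexion = glide_flexion, glide_width = 0.3),
            class = "kin_template")
}

#' Template waveform on the 100-point cycle grid
#'
#' @param template a [breaststroke_template()].
#' @param joint one of `"knee"`, `"hip"`, `"hip_abd"`, `"ankle"`.
#' @param leg `"L"` or `"R"` (applies that leg's amplitude scale).
#' @return numeric length-100 waveform, degrees.
#' @export
template_waveform <- function(template, joint, leg = "L") {
  b <- template$base[[joint]]
  p <- seq(0, 1, length.out = 100)
  w <- b$amp * template$rom_scale[[leg]][joint] * raised_cosine(p, b$center, b$width)
  if (joint == "knee")
    w <- w + glide_notch(p, template$glide_flexion, template$glide_width)
  w
}

#' Generate ground-truth breaststroke kinematics
#'
#' Draws per-stroke durations (stated CV), shifts the right leg by the
#' template phase lag (plus per-stroke jitter), scales amplitudes per
#' leg/joint, adds per-cycle amplitude jitter, and samples all joint
#' angles at `rate` Hz. The recording starts with a motionless standing
#' window of `static_lead` seconds (all joints neutral) for calibration.
#' The exact event times and the true values of every recoverable
#' parameter accompany the series.
#'
#' @param template a [breaststroke_template()].
#' @param n_strokes number of strokes (>= 2).
#' @param seed integer RNG seed.
#' @param rate sampling rate, Hz (default 200).
#' @param static_lead standing calibration lead-in, s (default 3).
#' @param velocity nominal swim velocity, m/s, used to construct
#'   consistent lap metadata (default 0.4).
#' @return list of class `kinematics`: `t`, `rate`, `angles` (nested
#'   `[[leg]][[joint]]` of `joint_angles`), `events` (per leg), `truth`,
#'   `lap`, `static_window`.
#' @export
generate_kinematics <- function(template, n_strokes, seed = 1, rate = 200,
                                static_lead = 3, velocity = 0.4) {
  stopifnot(inherits(template, "kin_template"), n_strokes >= 2)
  set.seed(seed)
  dur <- template$stroke_duration *
    pmax(0.4, 1 + template$duration_cv * stats::rnorm(n_strokes))
  ev_L <- static_lead + c(0, cumsum(dur))
  lag <- template$phase_lag +
    template$phase_lag_jitter * stats::rnorm(n_strokes + 1)
  lag <- pmax(-50, pmin(50, lag))
  ev_R <- ev_L + lag / 100 * c(dur, dur[n_strokes])
  t_end <- max(ev_L[n_strokes + 1], ev_R[n_strokes + 1]) + 0.5
  t <- seq(0, t_end, by = 1 / rate)
  joints <- names(template$base)
  jit <- array(template$cycle_jitter * stats::rnorm(n_strokes * 4 * 2),
               dim = c(n_strokes, 4, 2),
               dimnames = list(NULL, joints, c("L", "R")))

  leg_angles <- function(ev, leg) {
    cyc <- findInterval(t, ev)          # 0 before first event
    phase <- rep(0, length(t))
    act <- cyc >= 1 & cyc <= n_strokes
    phase[act] <- (t[act] - ev[cyc[act]]) / (ev[cyc[act] + 1] - ev[cyc[act]])
    out <- lapply(joints, function(j) {
      b <- template$base[[j]]
      amp <- rep(0, length(t))
      amp[act] <- b$amp * template$rom_scale[[leg]][j] + jit[cyc[act], j, leg]
      ang <- amp * raised_cosine(phase, b$center, b$width)
      if (j == "knee")
        ang[act] <- ang[act] + glide_notch(phase[act], template$glide_flexion,
                                           template$glide_width)
      ang[!act] <- 0
      structure(list(t = t, angle = ang,
                     joint = paste0(sub("_abd", "", j), "_", leg),
                     plane = if (j == "hip_abd") "abd_add" else "flex_ext",
                     leg = leg),
                class = "joint_angles")
    })
    names(out) <- joints
    out
  }
  angles <- list(L = leg_angles(ev_L, "L"), R = leg_angles(ev_R, "R"))
  events <- list(
    L = structure(data.frame(t = ev_L, index = findInterval(ev_L, t),
                             leg = "L"),
                  class = c("stroke_events", "data.frame")),
    R = structure(data.frame(t = ev_R, index = findInterval(ev_R, t),
                             leg = "R"),
                  class = c("stroke_events", "data.frame")))

  # true parameter values, from the noiseless series and exact events
  truth_rom <- lapply(c(L = "L", R = "R"), function(leg) {
    vapply(joints, function(j) {
      cyc <- normalize_cycles(angles[[leg]][[j]], events[[leg]])
      range_of_motion(cyc)$rom
    }, numeric(1))
  })
  t_start <- min(ev_L[1], ev_R[1])
  t_end <- max(ev_L[n_strokes + 1], ev_R[n_strokes + 1])
  # lap metadata consistent with the configured velocity; boundary times
  # play the role of the timed push-off / wall-touch of a real lap
  lap <- list(lap_length = velocity * (t_end - t_start), n_laps = 1,
              t_start = t_start, t_end = t_end)
  truth <- list(
    durations = dur, duration_mean = mean(dur),
    duration_cv = stats::sd(dur) / mean(dur),
    phase_lag = lag[seq_len(n_strokes)], rom = truth_rom,
    velocity = velocity)
  structure(list(t = t, rate = rate, angles = angles, events = events,
                 truth = truth, lap = lap,
                 static_window = c(0, static_lead),
                 template = template),
            class = "kinematics")
}

#' Sensor noise and mounting model
#'
#' @param gyro_noise_sd gyro white noise SD, rad/s (default 0.01).
#' @param accel_noise_sd accel white noise SD, m/s^2 (default 0.15).
#' @param gyro_bias_sd per-sensor constant gyro bias SD, rad/s
#'   (default 0.005).
#' @param mount_sd_deg SD of random constant mounting rotations, degrees
#'   (default 10).
#' @param rate sampling rate, Hz (default 200).
#' @return list of class `sensor_model`.
#' @export
sensor_model <- function(gyro_noise_sd = 0.01, accel_noise_sd = 0.15,
                         gyro_bias_sd = 0.005, mount_sd_deg = 10,
                         rate = 200) {
  stopifnot(gyro_noise_sd >= 0, accel_noise_sd >= 0, gyro_bias_sd >= 0,
            mount_sd_deg >= 0, rate > 0)
  structure(list(gyro_noise_sd = gyro_noise_sd,
                 accel_noise_sd = accel_noise_sd,
                 gyro_bias_sd = gyro_bias_sd,
                 mount_sd_deg = mount_sd_deg, rate = rate),
            class = "sensor_model")
}

#' Kinematic-chain geometry
#'
#' Segment lengths (anthropometric defaults) and the fractional position
#' of each sensor along its segment; these affect only the linear
#' acceleration terms and the true ankle displacement.
#'
#' @param thigh,shank,foot segment lengths, m.
#' @param thigh_frac,shank_frac,foot_frac sensor position as a fraction
#'   of segment length from the proximal end.
#' @return list of class `segment_geometry`.
#' @export
segment_geometry <- function(thigh = 0.42, shank = 0.43, foot = 0.20,
                             thigh_frac = 0.67, shank_frac = 0.9,
                             foot_frac = 0.5) {
  structure(list(thigh = thigh, shank = shank, foot = foot,
                 thigh_frac = thigh_frac, shank_frac = shank_frac,
                 foot_frac = foot_frac),
            class = "segment_geometry")
}

# standing orientation of every body segment in the fusion Earth frame
# (z up): body x points down, body y forward, body z to the right
R_STANDING <- matrix(c(0, 1, 0,
                       0, 0, -1,
                       -1, 0, 0), nrow = 3, byrow = TRUE)

#' Forward-simulate IMU streams from kinematics
#'
#' Composes segment orientations along the pelvis-thigh-shank-foot chain
#' (pelvis quasi-static on the kickboard), applies random constant
#' mounting rotations, and synthesizes per-sensor gyro (exact body-frame
#' angular increments plus bias and noise) and accelerometer signals
#' (gravity expressed in the sensor frame plus the segment's linear
#' acceleration from the kinematic chain, plus noise).
#'
#' @param kin a [generate_kinematics()] result.
#' @param model a [sensor_model()].
#' @param geometry a [segment_geometry()].
#' @param seed integer RNG seed for noise, biases and mounting offsets.
#' @param mounts optional named list of unit quaternions (one per
#'   placement) overriding the random mounting offsets.
#' @return list `streams` (named [sensor_stream()] list),
#'   `truth` (`q_segment` per placement, `ankle_pos` per leg, mounting
#'   offsets, biases).
#' @export
kinematics_to_imu <- function(kin, model = sensor_model(),
                              geometry = segment_geometry(), seed = 1,
                              mounts = NULL) {
  set.seed(seed)
  t <- kin$t
  n <- length(t)
  dt <- diff(t)
  q0 <- rotmat_to_quat(R_STANDING)
  deg2rad <- pi / 180

  seg_quats <- function(leg) {
    hip <- kin$angles[[leg]]$hip$angle * deg2rad
    abd <- kin$angles[[leg]]$hip_abd$angle * deg2rad
    knee <- kin$angles[[leg]]$knee$angle * deg2rad
    ankle <- kin$angles[[leg]]$ankle$angle * deg2rad
    thigh <- matrix(0, n, 4); shank <- matrix(0, n, 4); foot <- matrix(0, n, 4)
    for (k in seq_len(n)) {
      qt <- quat_raw_multiply(q0, quat_raw_multiply(
        quat_from_axis_angle(c(0, 0, 1), hip[k]),
        quat_from_axis_angle(c(0, 1, 0), abd[k])))
      qs <- quat_raw_multiply(qt, quat_from_axis_angle(c(0, 0, 1), -knee[k]))
      qf <- quat_raw_multiply(qs, quat_from_axis_angle(c(0, 0, 1), -ankle[k]))
      thigh[k, ] <- quat_normalize(qt)
      shank[k, ] <- quat_normalize(qs)
      foot[k, ] <- quat_normalize(qf)
    }
    list(thigh = thigh, shank = shank, foot = foot)
  }
  segs <- list(L = seg_quats("L"), R = seg_quats("R"))
  pelvis <- matrix(rep(q0, each = n), n, 4)

  # world positions of each sensor (hip joints offset laterally per leg)
  sensor_pos <- function(leg, segment) {
    s <- segs[[leg]]
    hip_off <- c(0, if (leg == "L") 0.09 else -0.09, 0)  # E0 y points left
    pos <- matrix(0, n, 3)
    for (k in seq_len(n)) {
      Rt <- quat_to_rotmat(s$thigh[k, ])
      if (segment == "thigh") {
        pos[k, ] <- hip_off + Rt %*% c(geometry$thigh_frac * geometry$thigh, 0, 0)
      } else {
        pk <- hip_off + Rt %*% c(geometry$thigh, 0, 0)
        Rs <- quat_to_rotmat(s$shank[k, ])
        if (segment == "shank") {
          pos[k, ] <- pk + Rs %*% c(geometry$shank_frac * geometry$shank, 0, 0)
        } else {
          pa <- pk + Rs %*% c(geometry$shank, 0, 0)
          Rf <- quat_to_rotmat(s$foot[k, ])
          pos[k, ] <- pa + Rf %*% c(geometry$foot_frac * geometry$foot, 0, 0)
        }
      }
    }
    pos
  }

  placements <- list(
    thigh_L = list(q = segs$L$thigh, pos = sensor_pos("L", "thigh")),
    thigh_R = list(q = segs$R$thigh, pos = sensor_pos("R", "thigh")),
    shank_L = list(q = segs$L$shank, pos = sensor_pos("L", "shank")),
    shank_R = list(q = segs$R$shank, pos = sensor_pos("R", "shank")),
    foot_L = list(q = segs$L$foot, pos = sensor_pos("L", "foot")),
    foot_R = list(q = segs$R$foot, pos = sensor_pos("R", "foot")),
    back_upper = list(q = pelvis, pos = matrix(0, n, 3)),
    back_lower = list(q = pelvis, pos = matrix(0, n, 3)))

  streams <- list()
  truth_q <- list()
  mounts_used <- list()
  biases <- list()
  for (nm in names(placements)) {
    pl <- placements[[nm]]
    mount <- if (!is.null(mounts)) quat_normalize(mounts[[nm]]) else
      quat_from_axis_angle(
        stats::rnorm(3),
        model$mount_sd_deg * deg2rad * stats::rnorm(1))
    bias <- model$gyro_bias_sd * stats::rnorm(3)
    qs <- t(vapply(seq_len(n), function(k) {
      quat_normalize(quat_raw_multiply(pl$q[k, ], mount))
    }, numeric(4)))
    # gyro: exact body-frame angular increment over (t[k-1], t[k]]
    gyro <- matrix(0, n, 3)
    for (k in 2:n) {
      dq <- quat_raw_multiply(quat_conjugate(qs[k - 1, ]), qs[k, ])
      gyro[k, ] <- quat_log(dq) / dt[k - 1]
    }
    # linear acceleration by central second difference of world position
    acc_w <- matrix(0, n, 3)
    if (n >= 3) {
      h <- 1 / kin$rate
      acc_w[2:(n - 1), ] <-
        (pl$pos[3:n, ] - 2 * pl$pos[2:(n - 1), ] + pl$pos[1:(n - 2), ]) / h^2
      acc_w[1, ] <- acc_w[2, ]; acc_w[n, ] <- acc_w[n - 1, ]
    }
    accel <- t(vapply(seq_len(n), function(k) {
      quat_rotate(quat_conjugate(qs[k, ]), acc_w[k, ] + c(0, 0, GRAVITY))
    }, numeric(3)))
    gyro <- gyro + matrix(bias, n, 3, byrow = TRUE) +
      model$gyro_noise_sd * matrix(stats::rnorm(3 * n), n, 3)
    accel <- accel + model$accel_noise_sd * matrix(stats::rnorm(3 * n), n, 3)
    streams[[nm]] <- sensor_stream(nm, t, gyro, accel, rate = kin$rate)
    truth_q[[nm]] <- quat_series(t, qs)
    mounts_used[[nm]] <- mount
    biases[[nm]] <- bias
  }
  ankle_pos <- list(L = sensor_pos("L", "shank"), R = sensor_pos("R", "shank"))
  list(streams = streams,
       truth = list(q_sensor = truth_q, ankle_pos = ankle_pos,
                    mounts = mounts_used, biases = biases))
}
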