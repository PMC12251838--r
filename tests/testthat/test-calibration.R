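test_that("relative rotation satisfies the algebraic definition", {
  t <- seq(0, 1, by = 0.05)
  n <- length(t)
  id <- matrix(rep(c(1, 0, 0, 0), n), n, 4, byrow = TRUE)
  s_id <- quat_series(t, id)
  expect_equal(relative_rotation(s_id, s_id)$q, id)
  q30 <- quat_from_axis_angle(c(0, 0, 1), 30 * pi / 180)
  s30 <- quat_series(t, matrix(rep(q30, n), n, 4, byrow = TRUE))
  expect_equal(relative_rotation(s_id, s30)$q[1, ], q30, tolerance = 1e-12)
  # random pair: R1 %*% R_rel == R2 at every sample
  set.seed(4)
  qa <- t(vapply(seq_len(n), function(k) quat_from_axis_angle(rnorm(3), runif(1, 0, 2)),
                 numeric(4)))
  qb <- t(vapply(seq_len(n), function(k) quat_from_axis_angle(rnorm(3), runif(1, 0, 2)),
                 numeric(4)))
  rel <- relative_rotation(quat_series(t, qa), quat_series(t, qb))
  for (k in c(1, 7, n)) {
    lhs <- quat_to_rotmat(qa[k, ]) %*% quat_to_rotmat(rel$q[k, ])
    expect_equal(lhs, quat_to_rotmat(qb[k, ]), tolerance = 1e-9)
  }
  expect_error(relative_rotation(s_id, quat_series(t[-1], qa[-1, ])), "mismatch")
})

test_that("yaw alignment zeroes relative heading and expresses gravity along +x", {
  # static subject: truth orientations with distinct mount rotations,
  # one of them 15 degrees in yaw relative to the reference
  t <- seq(0, 3, by = 0.01)
  n <- length(t)
  q_stand <- rotmat_to_quat(swimkin:::R_STANDING)
  yaws <- c(thigh_R = 0, thigh_L = 15, shank_L = -8, shank_R = 3,
            foot_L = 5, foot_R = -5, back_upper = 2, back_lower = -2)
  series <- lapply(names(yaws), function(nm) {
    q <- quat_multiply(q_stand,
                       quat_from_axis_angle(c(1, 0, 0), yaws[nm] * pi / 180))
    quat_series(t, matrix(rep(q, n), n, 4, byrow = TRUE))
  })
  names(series) <- names(yaws)
  aligned <- align_common_frame(series, c(0, 3))
  # relative yaw to the reference is zero over the static window
  yaw_of <- function(q) {
    R <- quat_to_rotmat(q)
    # heading about the vertical (x down in the aligned frame): use the
    # y axis (forward) projected on the horizontal (y, z) plane
    atan2(R[3, 2], R[2, 2]) * 180 / pi
  }
  y_ref <- yaw_of(aligned$thigh_R$q[1, ])
  for (nm in names(yaws))
    expect_lt(abs(yaw_of(aligned[[nm]]$q[1, ]) - y_ref), 0.1)
  # gravity (down) maps to +x in every aligned frame: the measured up
  # direction in sensor coordinates maps to -x through the aligned rotation
  for (nm in names(yaws)) {
    q_raw <- series[[nm]]$q[1, ]
    up_sensor <- quat_rotate(quat_conjugate(q_raw), c(0, 0, 1))
    up_aligned <- quat_rotate(aligned[[nm]]$q[1, ], up_sensor)
    expect_equal(up_aligned, c(-1, 0, 0), tolerance = 1e-9)
  }
  expect_error(align_common_frame(series[-1], c(0, 3)), "reference")
})

test_that("static calibration zeroes joint angles and removes mounting offsets", {
  tmpl <- breaststroke_template()
  kin <- generate_kinematics(tmpl, n_strokes = 3, seed = 11, static_lead = 3)
  clean <- sensor_model(0, 0, 0, 0)
  # perfectly mounted: offsets equal the standing orientation, and the
  # static knee angle is zero
  sim <- kinematics_to_imu(kin, model = clean, seed = 1,
                           mounts = identity_mounts())
  ja <- calibrate_and_angles(sim$truth$q_sensor, c(0.3, 2.7),
                             joints = "knee_R")
  stat <- ja$knee_R$flex_ext$angle[kin$t < 2.7]
  expect_lt(max(abs(stat)), 1e-6)
  # shank sensor pitched 12 degrees on the leg: static knee still ~0
  m <- identity_mounts()
  m$shank_R <- quat_from_axis_angle(c(0, 0, 1), 12 * pi / 180)
  sim12 <- kinematics_to_imu(kin, model = clean, seed = 1, mounts = m)
  ja12 <- calibrate_and_angles(sim12$truth$q_sensor, c(0.3, 2.7),
                               joints = "knee_R")
  expect_lt(max(abs(ja12$knee_R$flex_ext$angle[kin$t < 2.7])), 0.2)
})

test_that("joint angles are invariant to inclination-dominant mounting offsets", {
  tmpl <- breaststroke_template()
  kin <- generate_kinematics(tmpl, n_strokes = 3, seed = 11, static_lead = 3)
  clean <- sensor_model(0, 0, 0, 0)
  set.seed(21)
  sims <- lapply(1:2, function(i)
    kinematics_to_imu(kin, model = clean, seed = 1,
                      mounts = inclination_mounts()))
  jas <- lapply(sims, function(s)
    calibrate_and_angles(s$truth$q_sensor, c(0.3, 2.7)))
  for (j in c("knee_L", "knee_R", "hip_L", "hip_R")) {
    d <- max(abs(jas[[1]][[j]]$flex_ext$angle - jas[[2]][[j]]$flex_ext$angle))
    expect_lt(d, 0.5)
  }
})

test_that("single-axis rotations decompose into the expected planes and antisymmetry", {
  t <- seq(0, 3, by = 0.01)
  n <- length(t)
  q_stand <- rotmat_to_quat(swimkin:::R_STANDING)
  # thigh fixed at standing; shank rotated -45 deg about body z after a
  # static second (knee flexion is the negative z rotation of the distal
  # segment, reported positive)
  ang <- ifelse(t < 1.5, 0, 45 * pi / 180)
  thigh <- quat_series(t, matrix(rep(q_stand, n), n, 4, byrow = TRUE))
  shank <- quat_series(t, t(vapply(ang, function(a)
    quat_multiply(q_stand, quat_from_axis_angle(c(0, 0, 1), -a)),
    numeric(4))))
  series <- list(thigh_R = thigh, shank_R = shank,
                 thigh_L = thigh, shank_L = shank,
                 foot_L = shank, foot_R = shank,
                 back_upper = thigh, back_lower = thigh)
  ja <- calibrate_and_angles(series, c(0, 1), joints = "knee_R")
  expect_equal(ja$knee_R$flex_ext$angle[n], 45, tolerance = 1e-6)
  # identical frames give zero in all planes
  ja0 <- calibrate_and_angles(series, c(0, 1), joints = "hip_L")
  expect_lt(max(abs(ja0$hip_L$flex_ext$angle[t < 1.5])), 1e-6)
  # antisymmetry for a single-axis motion: swapping proximal and distal
  # negates the angle
  rel_ab <- relative_rotation(thigh, shank)
  rel_ba <- relative_rotation(shank, thigh)
  ez_ab <- swimkin:::euler_zyx(quat_to_rotmat(rel_ab$q[n, ]))$angles[1]
  ez_ba <- swimkin:::euler_zyx(quat_to_rotmat(rel_ba$q[n, ]))$angles[1]
  expect_equal(ez_ab, -ez_ba, tolerance = 1e-9)
})

test_that("full pipeline recovers the knee trajectory within 2 degrees (noiseless)", {
  tmpl <- breaststroke_template()
  kin <- generate_kinematics(tmpl, n_strokes = 4, seed = 5, static_lead = 3)
  sim <- kinematics_to_imu(kin, model = sensor_model(0, 0, 0, 0), seed = 2,
                           mounts = identity_mounts())
  cfg <- default_config()
  cfg$static_window <- c(0.3, 2.7)
  pipe <- swim_pipeline(sim$streams, cfg)
  rmse <- pipeline_rmse(kin, pipe)
  expect_lt(max(rmse[c("knee_L", "knee_R")]), 2)
  # and under 1 degree for the default gating configuration
  expect_lt(max(rmse), 1)
})
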