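events_at <- function(t, leg = "L") {
  structure(data.frame(t = t, index = NA_integer_, leg = leg),
            class = c("stroke_events", "data.frame"))
}

test_that("temporal parameters follow their definitions", {
  ev <- events_at(seq(0, 50, by = 2))
  tp <- temporal_params(ev, lap_length = 25, n_laps = 1)
  expect_equal(tp$stroke_duration_mean, 2)
  expect_equal(tp$stroke_duration_sd, 0)
  expect_equal(tp$stroke_rate, 30)
  expect_equal(tp$velocity, 0.5)
  expect_equal(tp$distance_per_stroke, 1)
  # no lap metadata: temporal parameters still computed, velocity NA
  tp2 <- temporal_params(ev, lap_length = NULL, n_laps = NULL)
  expect_true(is.na(tp2$velocity) && is.na(tp2$distance_per_stroke))
  expect_equal(tp2$stroke_rate, 30)
})

test_that("range of motion averages per-cycle excursions", {
  m <- structure(rbind(seq(10, 80, length.out = 100),
                       seq(20, 70, length.out = 100)),
                 class = c("normalized_cycles", "matrix"))
  r <- range_of_motion(m)
  expect_equal(r$rom, mean(c(70, 50)))
  expect_equal(range_of_motion(m[1, , drop = FALSE])$rom, 70)
  const <- structure(matrix(5, 1, 100), class = c("normalized_cycles", "matrix"))
  expect_equal(range_of_motion(const)$rom, 0)
})

test_that("cyclogram centering is idempotent and translation-invariant", {
  th <- seq(0, 2 * pi, length.out = 100)
  circ <- build_cyclogram(20 * cos(th) + 13, 20 * sin(th) - 7)
  c1 <- center_cyclogram(circ)
  expect_equal(mean(c1$x), 0, tolerance = 1e-9)
  expect_equal(mean(c1$y), 0, tolerance = 1e-9)
  expect_equal(center_cyclogram(c1), c1)
  shifted <- build_cyclogram(circ$x + 31, circ$y - 12)
  expect_equal(center_cyclogram(shifted)$x, c1$x, tolerance = 1e-9)
  expect_error(build_cyclogram(1:50, 1:50), "100-point")
})

test_that("SSD is a symmetric, nonnegative shape distance, zero iff identical", {
  set.seed(8)
  mk <- function() center_cyclogram(build_cyclogram(rnorm(100), rnorm(100)))
  a <- mk(); b <- mk()
  expect_equal(cyclogram_ssd(a, a), 0)
  expect_gt(cyclogram_ssd(a, b), 0)
  expect_equal(cyclogram_ssd(a, b), cyclogram_ssd(b, a))
  # doubling a centered cyclogram: SSD equals the sum of squared radii
  a2 <- a; a2$x <- 2 * a$x; a2$y <- 2 * a$y
  expect_equal(cyclogram_ssd(a, a2), sum(a$x^2 + a$y^2), tolerance = 1e-9)
  expect_error(cyclogram_ssd(a, build_cyclogram(rnorm(100), rnorm(100))),
               "centered")
})

test_that("asymmetry SSD equals the SSD of mean cyclograms and grows with deficits", {
  wf_k <- template_waveform(breaststroke_template(), "knee")
  wf_a <- template_waveform(breaststroke_template(), "ankle")
  mk_leg <- function(scale) lapply(1:5, function(i)
    center_cyclogram(build_cyclogram(wf_a * scale, wf_k * scale)))
  left <- mk_leg(1); right <- mk_leg(1)
  expect_equal(asymmetry_ssd(left, right), 0)
  expect_equal(asymmetry_ssd(left, mk_leg(0.8)),
               cyclogram_ssd(mean_cyclogram(left), mean_cyclogram(mk_leg(0.8))))
  deficits <- c(0.95, 0.85, 0.7)
  vals <- vapply(deficits, function(d) asymmetry_ssd(left, mk_leg(d)), numeric(1))
  expect_true(all(diff(vals) > 0))
})

test_that("ACC is 1 for identical cycles, near 0 for random ones, bounded in [0,1]", {
  wf_k <- template_waveform(breaststroke_template(), "knee")
  wf_a <- template_waveform(breaststroke_template(), "ankle")
  same <- lapply(1:20, function(i) build_cyclogram(wf_a, wf_k))
  expect_identical(cyclogram_acc(same), 1)
  # uniformly random directions: consistency vanishes as cycles grow
  set.seed(31)
  rand <- lapply(1:200, function(i)
    build_cyclogram(cumsum(rnorm(100)), cumsum(rnorm(100))))
  acc_rand <- cyclogram_acc(rand)
  expect_lt(acc_rand, 0.15)
  expect_gte(acc_rand, 0)
  jittered <- lapply(1:10, function(i)
    build_cyclogram(wf_a + rnorm(100), wf_k + rnorm(100)))
  expect_true(cyclogram_acc(jittered) >= 0 && cyclogram_acc(jittered) <= 1)
})

test_that("ACC matches a brute-force circular-statistics oracle", {
  set.seed(17)
  cyclos <- lapply(1:5, function(i)
    build_cyclogram(cumsum(rnorm(100)), cumsum(rnorm(100))))
  # independent elementwise computation
  acc_oracle <- local({
    a_i <- numeric(99)
    for (i in 1:99) {
      cs <- sn <- 0
      for (k in 1:5) {
        dx <- cyclos[[k]]$x[i + 1] - cyclos[[k]]$x[i]
        dy <- cyclos[[k]]$y[i + 1] - cyclos[[k]]$y[i]
        th <- atan2(dy, dx)
        cs <- cs + cos(th); sn <- sn + sin(th)
      }
      a_i[i] <- sqrt((cs / 5)^2 + (sn / 5)^2)
    }
    mean(a_i)
  })
  expect_equal(cyclogram_acc(cyclos), acc_oracle, tolerance = 1e-12)
})

test_that("phase shift measures inter-limb timing offsets in cycle percent", {
  L <- events_at(seq(0, 20, by = 2), "L")
  expect_equal(phase_shift(L, L)$mean, 0)
  R <- events_at(seq(0, 20, by = 2) + 0.2, "R")
  ps <- phase_shift(L, R)
  expect_equal(ps$mean, 10, tolerance = 1e-9)
  # wrapped: a 1.8 s delay on 2 s strokes is a -10% shift, |.| = 10
  R2 <- events_at(seq(0, 20, by = 2) + 1.8, "R")
  expect_equal(phase_shift(L, R2)$mean, 10, tolerance = 1e-9)
  expect_error(phase_shift(L, events_at(c(100, 102), "R")), "overlap")
})

test_that("asymmetry percentage is symmetric and normalized by the mean", {
  expect_equal(asymmetry_pct(90, 90), 0)
  expect_equal(asymmetry_pct(90, 110), 20)
  expect_equal(asymmetry_pct(110, 90), 20)
  expect_equal(asymmetry_pct(0, 0), 0)
})

test_that("ankle displacement double-integration recovers known motion", {
  rate <- 200
  t <- seq(0, 2, by = 1 / rate)
  n <- length(t)
  id <- matrix(rep(c(1, 0, 0, 0), n), n, 4, byrow = TRUE)
  orient <- quat_series(t, id)
  win <- data.frame(t0 = 0, t1 = 2)
  # zero linear acceleration: zero displacement. In the aligned Earth
  # frame x points down, so a resting sensor at identity reads -g on x.
  still <- sensor_stream("shank_L", t, matrix(0, n, 3),
                         matrix(rep(c(-GRAV, 0, 0), n), n, 3, byrow = TRUE))
  d0 <- ankle_displacement(still, orient, win)
  expect_lt(max(abs(c(d0$vertical, d0$horizontal, d0$lateral))), 1e-9)
  # lateral oscillation z = 0.15 cos(wt) over one full period (velocity
  # zero at the window ends, as the propulsion windowing assumes):
  # peak-to-peak 0.30 m on the lateral (z) axis
  w <- 2 * pi / 2
  az <- -0.15 * w^2 * cos(w * t)
  acc <- cbind(rep(-GRAV, n), 0, az)
  moving <- sensor_stream("shank_L", t, matrix(0, n, 3), acc)
  d1 <- ankle_displacement(moving, orient, win)
  expect_equal(d1$lateral, 0.30, tolerance = 0.03)
  expect_lt(abs(d1$horizontal), 0.02)
  # rotating sensor under pure gravity: leakage below 2 cm
  qpath <- t(vapply(t, function(tt)
    quat_from_axis_angle(c(0, 0, 1), 0.5 * sin(w * tt)), numeric(4)))
  grav_sensor <- t(vapply(seq_len(n), function(k)
    quat_rotate(quat_conjugate(qpath[k, ]), c(-GRAV, 0, 0)), numeric(3)))
  rot <- sensor_stream("shank_L", t, matrix(0, n, 3), grav_sensor)
  d2 <- ankle_displacement(rot, quat_series(t, qpath), win)
  expect_lt(max(abs(c(d2$vertical, d2$horizontal, d2$lateral))), 0.02)
  # short windows are skipped
  expect_error(ankle_displacement(still, orient, data.frame(t0 = 0, t1 = 0.05)),
               "no usable")
})

test_that("z-scoring maps the healthy reference to zero mean and unit SD", {
  mu <- c(a = 10, b = 0.5)
  sigma <- c(a = 2, b = 0.1)
  expect_equal(as.numeric(zscore_profile(c(a = 10, b = 0.5), mu, sigma)),
               c(0, 0))
  expect_equal(as.numeric(zscore_profile(c(a = 12, b = 0.6), mu, sigma)),
               c(1, 1))
  # a healthy cohort z-scored against itself: per-parameter mean 0, SD 1
  set.seed(2)
  cohort <- cbind(a = rnorm(30, 10, 2), b = rnorm(30, 0.5, 0.1))
  ref <- healthy_reference(cohort)
  z <- t(apply(cohort, 1, zscore_profile, mu = ref$mu, sigma = ref$sigma))
  expect_equal(unname(colMeans(z)), c(0, 0), tolerance = 1e-9)
  expect_equal(unname(apply(z, 2, sd)), c(1, 1), tolerance = 1e-9)
  expect_error(zscore_profile(c(a = 1), c(a = 0), c(a = 0)), "a")
})
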