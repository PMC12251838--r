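#' Spatiotemporal swimming parameters
#'
#' All per-stroke parameters are reported as the mean over all strokes;
#' standard deviations across strokes are reported for stroke duration,
#' ACC and phase shift as variability measures.
#'
#' @name parameters
NULL

#' Temporal swimming parameters
#'
#' Stroke duration is the time between consecutive cycle-start events
#' (glide phases); stroke rate is 60 / mean duration; velocity is total
#' distance over the event-bounded active time; distance per stroke is
#' velocity times the mean stroke duration. With no lap metadata the
#' temporal parameters are still computed and velocity / distance per
#' stroke are `NA`.
#'
#' @param events `stroke_events` for one leg (or pooled).
#' @param lap_length lap length in metres (default 5), or `NULL`.
#' @param n_laps number of completed laps, or `NULL`.
#' @return list: `stroke_duration_mean`, `stroke_duration_sd`,
#'   `stroke_rate`, `velocity`, `distance_per_stroke`.
#' @export
temporal_params <- function(events, lap_length = 5, n_laps = NULL) {
  if (nrow(events) < 2) stop("need at least 2 events")
  dur <- diff(events$t)
  dm <- mean(dur)
  out <- list(stroke_duration_mean = dm,
              stroke_duration_sd = stats::sd(dur),
              stroke_rate = 60 / dm,
              velocity = NA_real_,
              distance_per_stroke = NA_real_)
  if (!is.null(lap_length) && !is.null(n_laps)) {
    stopifnot(lap_length > 0, n_laps > 0)
    active <- events$t[nrow(events)] - events$t[1]
    out$velocity <- lap_length * n_laps / active
    out$distance_per_stroke <- out$velocity * dm
  }
  out
}

#' Range of motion and joint extrema
#'
#' Per-cycle max minus min, averaged over cycles; extrema are the means
#' of the per-cycle minima and maxima.
#'
#' @param cycles a `normalized_cycles` matrix.
#' @return list `rom`, `angle_min`, `angle_max` (degrees).
#' @export
range_of_motion <- function(cycles) {
  stopifnot(nrow(cycles) >= 1)
  mins <- apply(cycles, 1, min)
  maxs <- apply(cycles, 1, max)
  list(rom = mean(maxs - mins), angle_min = mean(mins), angle_max = mean(maxs))
}

#' Build an angle-angle cyclogram
#'
#' Pairs two normalized 100-point cycles of the same leg and cycle
#' (e.g. ankle-knee or knee-hip sagittal angles).
#'
#' @param cycle_x,cycle_y numeric length-100 angle vectors (degrees).
#' @param pair label, e.g. `"ankle_knee"`.
#' @param leg `"L"` or `"R"`.
#' @return object of class `cyclogram`: list `x`, `y`, `pair`, `leg`,
#'   `centered`.
#' @export
build_cyclogram <- function(cycle_x, cycle_y, pair = "ankle_knee", leg = "L") {
  if (length(cycle_x) != 100L || length(cycle_y) != 100L)
    stop("cyclogram requires two 100-point cycles on the same grid")
  structure(list(x = as.numeric(cycle_x), y = as.numeric(cycle_y),
                 pair = pair, leg = leg, centered = FALSE),
            class = "cyclogram")
}

#' Center a cyclogram on the origin
#'
#' Subtracts the centroid so that shape comparisons (SSD) are invariant
#' to angular offsets. Idempotent.
#'
#' @param c a [build_cyclogram()] object.
#' @return centered `cyclogram`.
#' @export
center_cyclogram <- function(c) {
  c$x <- c$x - mean(c$x)
  c$y <- c$y - mean(c$y)
  c$centered <- TRUE
  c
}

#' Pointwise mean of a set of cyclograms
#'
#' @param cyclos list of `cyclogram` objects on the same grid/pair/leg.
#' @return a `cyclogram` (centered flag inherited if all inputs centered).
#' @export
mean_cyclogram <- function(cyclos) {
  stopifnot(length(cyclos) >= 1)
  x <- rowMeans(vapply(cyclos, `[[`, numeric(100), "x"))
  y <- rowMeans(vapply(cyclos, `[[`, numeric(100), "y"))
  out <- build_cyclogram(x, y, cyclos[[1]]$pair, cyclos[[1]]$leg)
  out$centered <- all(vapply(cyclos, `[[`, logical(1), "centered"))
  out
}

#' Sum of squared distances between two centered cyclograms
#'
#' SSD = sum over the 100 grid points of the squared Euclidean distance
#' between corresponding points, in squared degrees. Zero iff the shapes
#' are identical; symmetric; requires centered inputs.
#'
#' @param c1,c2 centered `cyclogram` objects.
#' @return SSD in deg^2.
#' @export
cyclogram_ssd <- function(c1, c2) {
  if (!isTRUE(c1$centered) || !isTRUE(c2$centered))
    stop("SSD requires centered cyclograms")
  sum((c1$x - c2$x)^2 + (c1$y - c2$y)^2)
}

#' Inter-leg asymmetry SSD
#'
#' SSD between the mean left-leg and mean right-leg cyclograms: the
#' deviation of intra-limb coordination between the legs, deg^2.
#'
#' @param left,right lists of centered `cyclogram` objects per leg.
#' @return asymmetry SSD in deg^2.
#' @export
asymmetry_ssd <- function(left, right) {
  cyclogram_ssd(mean_cyclogram(left), mean_cyclogram(right))
}

#' Angular component of the coefficient of correspondence (ACC)
#'
#' Vector-coding consistency of cyclogram trajectories across cycles.
#' For each of the 99 consecutive point pairs i, the frame-to-frame
#' direction theta_{k,i} = atan2(dy, dx) is computed per cycle k; the
#' mean resultant length a_i = sqrt(mean(cos)^2 + mean(sin)^2) across
#' cycles measures directional agreement at i; ACC is the mean of a_i
#' over i. 1 = perfectly repeatable coordination pattern, 0 = no
#' consistency. Zero-length segments are excluded from their point's
#' mean; grid points with no usable segment are excluded from the outer
#' mean.
#'
#' @param cyclos list of >= 2 `cyclogram` objects (same pair/leg).
#' @param detail if TRUE, also return the SD of the pointwise
#'   consistencies a_i (the ACC variability across the cycle) and the
#'   a_i themselves.
#' @return ACC in \[0, 1\], or (with `detail`) list `acc`, `sd`, `a`.
#' @export
cyclogram_acc <- function(cyclos, detail = FALSE) {
  stopifnot(length(cyclos) >= 2)
  X <- vapply(cyclos, `[[`, numeric(100), "x")  # 100 x n_cycles
  Y <- vapply(cyclos, `[[`, numeric(100), "y")
  dx <- diff(X); dy <- diff(Y)                  # 99 x n_cycles
  len <- sqrt(dx^2 + dy^2)
  a <- vapply(seq_len(99), function(i) {
    ok <- len[i, ] > 0
    if (!any(ok)) return(NA_real_)
    th <- atan2(dy[i, ok], dx[i, ok])
    sqrt(mean(cos(th))^2 + mean(sin(th))^2)
  }, numeric(1))
  if (detail)
    list(acc = mean(a, na.rm = TRUE), sd = stats::sd(a[!is.na(a)]), a = a)
  else
    mean(a, na.rm = TRUE)
}

#' Inter-limb phase shift (phase dispersion)
#'
#' For each left-leg cycle-start event, the signed offset of the nearest
#' right-leg event divided by the current left stroke duration, as a
#' percentage wrapped to \[-50, +50\]. The mean of absolute values is the
#' phase shift (0% = perfect synchronization); the SD of the absolute
#' values across strokes is its variability.
#'
#' @param events_L,events_R `stroke_events` per leg.
#' @return list `mean`, `sd`, `per_stroke` (signed, %).
#' @export
phase_shift <- function(events_L, events_R) {
  if (nrow(events_L) < 2 || nrow(events_R) < 2)
    stop("need at least 2 events per leg")
  if (min(events_R$t) > max(events_L$t) || min(events_L$t) > max(events_R$t))
    stop("left and right event series do not overlap in time")
  shifts <- vapply(seq_len(nrow(events_L) - 1), function(k) {
    tl <- events_L$t[k]
    dur <- events_L$t[k + 1] - tl
    dtr <- events_R$t - tl
    off <- dtr[which.min(abs(dtr))]
    s <- off / dur * 100
    ((s + 50) %% 100) - 50
  }, numeric(1))
  list(mean = mean(abs(shifts)), sd = stats::sd(abs(shifts)),
       per_stroke = shifts)
}

#' Left-right asymmetry percentage
#'
#' 100 * |rom_L - rom_R| / mean(rom_L, rom_R); 0 when both are zero.
#' Symmetric in the legs.
#'
#' @param rom_L,rom_R range of motion per leg, degrees.
#' @return asymmetry in percent.
#' @export
asymmetry_pct <- function(rom_L, rom_R) {
  if (rom_L == 0 && rom_R == 0) return(0)
  100 * abs(rom_L - rom_R) / ((rom_L + rom_R) / 2)
}

#' Ankle displacement during propulsion
#'
#' Rotates the shank-worn ankle sensor's accelerometer into the Earth
#' frame, subtracts gravity, and double-integrates within each propulsion
#' window (peak knee flexion to the next maximum knee extension). A
#' linear velocity de-drift constrains the integrated velocity to zero at
#' both window ends (the segment is momentarily quasi-stationary at peak
#' flexion and in the glide). Reported per Earth axis as the mean
#' peak-to-peak displacement over strokes. In the aligned Earth
#' convention the x-axis is vertical (gravity), y is the swim direction
#' (horizontal) and z is lateral.
#'
#' @param stream the ankle (shank) [sensor_stream()].
#' @param orientation aligned [quat_series()] for that sensor.
#' @param windows data frame with columns `t0`, `t1` (propulsion windows).
#' @param min_window minimum usable window length, s (default 0.2).
#' @return list `vertical`, `horizontal`, `lateral` (m), `n_windows`.
#' @export
ankle_displacement <- function(stream, orientation, windows,
                               min_window = 0.2) {
  stopifnot(length(stream$t) == length(orientation$t))
  n <- length(stream$t)
  # specific force in Earth frame, minus gravity reaction (up = -x, since
  # the aligned Earth x-axis points down)
  a_E <- t(vapply(seq_len(n), function(k) {
    quat_rotate(orientation$q[k, ], stream$accel[k, ])
  }, numeric(3)))
  a_E[, 1] <- a_E[, 1] + GRAVITY
  pp <- matrix(NA_real_, 0, 3)
  for (w in seq_len(nrow(windows))) {
    sel <- which(stream$t >= windows$t0[w] & stream$t <= windows$t1[w])
    if (length(sel) < 3) next
    tw <- stream$t[sel]
    if (tw[length(tw)] - tw[1] < min_window) next
    dt <- diff(tw)
    disp <- matrix(0, length(sel), 3)
    for (ax in 1:3) {
      v <- c(0, cumsum((a_E[sel[-length(sel)], ax] + a_E[sel[-1], ax]) / 2 * dt))
      # de-drift: linear velocity correction so v = 0 at both ends
      v <- v - seq(0, 1, length.out = length(v)) * v[length(v)]
      disp[, ax] <- c(0, cumsum((v[-length(v)] + v[-1]) / 2 * dt))
    }
    pp <- rbind(pp, apply(disp, 2, function(d) diff(range(d))))
  }
  if (nrow(pp) == 0) stop("no usable propulsion windows")
  list(vertical = mean(pp[, 1]), horizontal = mean(pp[, 2]),
       lateral = mean(pp[, 3]), n_windows = nrow(pp))
}

#' Propulsion windows from knee events and angles
#'
#' The propulsion phase runs from peak knee flexion within a cycle to the
#' cycle's end (the next maximum knee extension), when the legs extend
#' and generate thrust.
#'
#' @param knee sagittal knee `joint_angles`.
#' @param events `stroke_events` for the same leg.
#' @return data frame with columns `t0`, `t1`.
#' @export
propulsion_windows <- function(knee, events) {
  out <- lapply(seq_len(nrow(events) - 1), function(k) {
    sel <- which(knee$t >= events$t[k] & knee$t < events$t[k + 1])
    if (length(sel) < 3) return(NULL)
    pk <- sel[which.max(knee$angle[sel])]
    data.frame(t0 = knee$t[pk], t1 = events$t[k + 1])
  })
  do.call(rbind, out[!vapply(out, is.null, logical(1))])
}

#' z-scored swim profile
#'
#' Standardizes a parameter vector against a healthy reference:
#' Z = (x - mu) / sigma per parameter. A value equal to the healthy mean
#' maps to 0; the magnitude is the number of healthy SDs from the mean.
#'
#' @param params named numeric vector of parameters.
#' @param mu,sigma named numeric vectors of the healthy reference mean
#'   and SD (names must cover `params`; sigma > 0).
#' @return named numeric vector of z-scores (class `swim_profile`).
#' @export
zscore_profile <- function(params, mu, sigma) {
  nm <- names(params)
  if (is.null(nm)) stop("params must be named")
  if (!all(nm %in% names(mu)) || !all(nm %in% names(sigma)))
    stop("reference mean/SD missing for some parameters")
  bad <- nm[sigma[nm] == 0]
  if (length(bad))
    stop("zero reference SD for parameter(s): ", paste(bad, collapse = ", "))
  z <- (params - mu[nm]) / sigma[nm]
  structure(z, class = "swim_profile")
}

#' Healthy reference from a cohort parameter matrix
#'
#' @param params_matrix subjects x parameters numeric matrix (healthy
#'   cohort).
#' @return list `mu`, `sigma` (named vectors).
#' @export
healthy_reference <- function(params_matrix) {
  list(mu = colMeans(params_matrix),
       sigma = apply(params_matrix, 2, stats::sd))
}
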