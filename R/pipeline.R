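#' End-to-end processing
#'
#' `swim_pipeline()` turns eight raw sensor streams into calibrated
#' segment orientations and joint angles; `swim_parameter_set()`
#' assembles the full swimming-parameter vector from joint angles and
#' stroke events; `analyze_trial()` chains the two with event detection.
#'
#' @name pipeline
NULL

#' Default session configuration
#'
#' @return named list of processing defaults: static calibration window,
#'   filter gains, reference sensor, lap metadata, event-detection
#'   thresholds and the analysis seed. All values can be overridden via a
#'   YAML session config ([read_session_config()]).
#' @export
default_config <- function() {
  list(rate = 200,
       static_window = c(0.5, 2.5),
       lap_length = 5,
       n_laps = NULL,
       beta = 0.1,
       beta_static = 2,
       reference = "thigh_R",
       gyro_rms_max = 0.1,
       accel_gate = 0.3,
       min_prominence = 10,
       min_period = 1,
       target_variance = 0.70,
       seed = 1)
}

#' Raw streams to calibrated joint angles
#'
#' Static attitude initialization, gradient-descent sensor fusion (high
#' gain inside the static window, movement gain outside), common-frame
#' alignment to the reference sensor, sensor-to-segment calibration, and
#' Euler joint angles for both ankles, knees and hips.
#'
#' @param streams named list of the eight [sensor_stream()]s.
#' @param config list as from [default_config()].
#' @return list: `angles` (nested per joint/plane `joint_angles`),
#'   `segments` (calibrated segment [quat_series()]), `aligned` (aligned
#'   sensor series), `offsets`, `config`.
#' @export
swim_pipeline <- function(streams, config = default_config()) {
  missing <- setdiff(swim_placements(), names(streams))
  if (length(missing))
    stop("missing sensor stream(s): ", paste(missing, collapse = ", "))
  sw <- config$static_window
  fused <- lapply(streams, function(s) {
    q0 <- static_attitude_init(s, sw, gyro_rms_max = config$gyro_rms_max)
    fuse_orientation(s, beta = config$beta, q0 = q0,
                     beta_window = list(window = sw, beta = config$beta_static),
                     accel_gate = config$accel_gate)
  })
  aligned <- align_common_frame(fused, sw, reference = config$reference)
  offsets <- lapply(aligned, sensor_to_segment_offset, static_window = sw)
  segments <- mapply(apply_segment_offset, aligned, offsets,
                     SIMPLIFY = FALSE)
  specs <- joint_specs()
  angles <- lapply(seq_len(nrow(specs)), function(i) {
    joint_angles(segments[[specs$proximal[i]]], segments[[specs$distal[i]]],
                 specs$joint[i])
  })
  names(angles) <- specs$joint
  list(angles = angles, segments = segments, aligned = aligned,
       offsets = offsets, config = config)
}

# nested per-leg angle list (knee/hip/hip_abd/ankle) from pipeline output
angles_by_leg <- function(angles) {
  lapply(c(L = "L", R = "R"), function(leg) {
    list(knee = angles[[paste0("knee_", leg)]]$flex_ext,
         hip = angles[[paste0("hip_", leg)]]$flex_ext,
         hip_abd = angles[[paste0("hip_", leg)]]$abd_add,
         ankle = angles[[paste0("ankle_", leg)]]$flex_ext)
  })
}

#' Assemble the full swimming-parameter set
#'
#' Computes every swimming parameter from per-leg joint-angle series and
#' stroke events: temporal parameters (stroke durations pooled over both
#' legs; velocity from lap metadata over the event-bounded active time),
#' joint extrema and range of motion, cyclogram ACC (mean and SD of the
#' pointwise directional consistencies), SSD against a healthy reference
#' cyclogram, left-right asymmetry, asymmetry SSD, phase shift, and
#' (when streams and orientations are supplied) ankle displacement
#' during propulsion.
#'
#' @param angles nested list `[[leg]][[joint]]` of `joint_angles`
#'   (joints `knee`, `hip`, `hip_abd`, `ankle`).
#' @param events list with `stroke_events` elements `L` and `R`.
#' @param lap list `lap_length`, `n_laps`, or `NULL` (velocity reported
#'   `NA`).
#' @param reference optional named list of centered reference
#'   `cyclogram`s (`ankle_knee`, `knee_hip`); SSD is `NA` without it.
#' @param ankle optional list per leg: `list(L = list(stream,
#'   orientation), R = ...)` of the shank sensors, for displacement.
#' @return list of class `swim_parameters`: `params` (named numeric
#'   vector), `cycles`, `cyclograms`, `events`.
#' @export
swim_parameter_set <- function(angles, events, lap = NULL,
                               reference = NULL, ankle = NULL) {
  dur <- c(diff(events$L$t), diff(events$R$t))
  p <- c(stroke_duration_mean = mean(dur),
         stroke_duration_sd = stats::sd(dur),
         stroke_rate = 60 / mean(dur))
  if (!is.null(lap) && !is.null(lap$n_laps)) {
    # active swim time: configured lap boundary times when available,
    # otherwise the event-bounded range
    active <- if (!is.null(lap$t_start) && !is.null(lap$t_end))
      lap$t_end - lap$t_start
    else max(events$L$t, events$R$t) - min(events$L$t, events$R$t)
    p["velocity"] <- lap$lap_length * lap$n_laps / active
    p["distance_per_stroke"] <- unname(p["velocity"] * p["stroke_duration_mean"])
  } else {
    p["velocity"] <- NA_real_
    p["distance_per_stroke"] <- NA_real_
  }

  cycles <- lapply(c(L = "L", R = "R"), function(leg) {
    lapply(angles[[leg]], normalize_cycles, events = events[[leg]])
  })
  for (leg in c("L", "R")) for (j in c("ankle", "knee", "hip")) {
    rm_ <- range_of_motion(cycles[[leg]][[j]])
    p[paste0("rom_", j, "_", leg)] <- rm_$rom
    p[paste0("min_", j, "_", leg)] <- rm_$angle_min
    p[paste0("max_", j, "_", leg)] <- rm_$angle_max
  }
  for (j in c("ankle", "knee", "hip"))
    p[paste0("asym_", j)] <- asymmetry_pct(p[paste0("rom_", j, "_L")],
                                           p[paste0("rom_", j, "_R")])

  pairs <- list(ankle_knee = c("ankle", "knee"), knee_hip = c("knee", "hip"))
  cyclograms <- list()
  for (pr in names(pairs)) {
    for (leg in c("L", "R")) {
      cx <- cycles[[leg]][[pairs[[pr]][1]]]
      cy <- cycles[[leg]][[pairs[[pr]][2]]]
      ncyc <- min(nrow(cx), nrow(cy))
      cgs <- lapply(seq_len(ncyc), function(k)
        build_cyclogram(cx[k, ], cy[k, ], pair = pr, leg = leg))
      cyclograms[[pr]][[leg]] <- cgs
      a <- cyclogram_acc(cgs, detail = TRUE)
      p[paste0("acc_", pr, "_", leg)] <- a$acc
      p[paste0("acc_sd_", pr, "_", leg)] <- a$sd
      p[paste0("ssd_", pr, "_", leg)] <- if (is.null(reference)) NA_real_ else
        cyclogram_ssd(center_cyclogram(mean_cyclogram(cgs)), reference[[pr]])
    }
    p[paste0("asym_ssd_", pr)] <- asymmetry_ssd(
      lapply(cyclograms[[pr]]$L, center_cyclogram),
      lapply(cyclograms[[pr]]$R, center_cyclogram))
  }

  ps <- phase_shift(events$L, events$R)
  p["phase_shift_mean"] <- ps$mean
  p["phase_shift_sd"] <- ps$sd

  if (!is.null(ankle)) {
    disp <- lapply(c(L = "L", R = "R"), function(leg) {
      win <- propulsion_windows(angles[[leg]]$knee, events[[leg]])
      ankle_displacement(ankle[[leg]]$stream, ankle[[leg]]$orientation, win)
    })
    p["ankle_disp_vertical"] <- mean(c(disp$L$vertical, disp$R$vertical))
    p["ankle_disp_horizontal"] <- mean(c(disp$L$horizontal, disp$R$horizontal))
    p["ankle_disp_lateral"] <- mean(c(disp$L$lateral, disp$R$lateral))
  }
  structure(list(params = p, cycles = cycles, cyclograms = cyclograms,
                 events = events),
            class = "swim_parameters")
}

#' @export
print.swim_parameters <- function(x, ...) {
  cat("<swim_parameters>\n")
  print(round(x$params, 3))
  invisible(x)
}

#' Analyze one swimming trial end to end
#'
#' Runs [swim_pipeline()], detects stroke events on each leg's sagittal
#' knee angle, and assembles the swimming-parameter set. Event detection
#' is restricted to times after the static calibration window.
#'
#' @param streams named list of the eight [sensor_stream()]s.
#' @param config list as from [default_config()].
#' @param reference optional centered reference cyclograms (see
#'   [swim_parameter_set()]).
#' @return the [swim_parameter_set()] result, plus elements `pipeline`
#'   (orientations and angles).
#' @export
analyze_trial <- function(streams, config = default_config(),
                          reference = NULL) {
  pipe <- swim_pipeline(streams, config)
  ab <- angles_by_leg(pipe$angles)
  move_win <- c(config$static_window[2] + 0.5, Inf)
  events <- lapply(ab, function(a)
    detect_stroke_events(a$knee, min_prominence = config$min_prominence,
                         min_period = config$min_period, window = move_win))
  lap <- if (is.null(config$n_laps)) NULL else
    list(lap_length = config$lap_length, n_laps = config$n_laps,
         t_start = config$lap_boundaries[1], t_end = config$lap_boundaries[2])
  ankle <- lapply(c(L = "L", R = "R"), function(leg) {
    nm <- paste0("shank_", leg)
    list(stream = streams[[nm]], orientation = pipe$aligned[[nm]])
  })
  out <- swim_parameter_set(ab, events, lap = lap, reference = reference,
                            ankle = ankle)
  out$pipeline <- pipe
  out
}

#' Reference cyclograms from a kinematic template
#'
#' Centered ankle-knee and knee-hip cyclograms of the template's
#' unimpaired waveform: the healthy reference shape used for SSD.
#'
#' @param template a [breaststroke_template()] (default: unimpaired).
#' @return named list of centered `cyclogram`s.
#' @export
reference_cyclograms <- function(template = breaststroke_template()) {
  wf <- lapply(c(ankle = "ankle", knee = "knee", hip = "hip"),
               function(j) template_waveform(template, j, "L"))
  list(ankle_knee = center_cyclogram(
         build_cyclogram(wf$ankle, wf$knee, "ankle_knee", "L")),
       knee_hip = center_cyclogram(
         build_cyclogram(wf$knee, wf$hip, "knee_hip", "L")))
}
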