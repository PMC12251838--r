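#' Stroke-cycle segmentation
#'
#' Breaststroke cycles start at maximum knee extension, i.e. at local
#' minima of the sagittal knee flexion angle. Detection runs on a
#' zero-lag low-pass filtered copy of the signal; cycles are the half-open
#' intervals between consecutive events and are resampled to 100 points
#' on a uniform cycle-percentage grid.
#'
#' @name segmentation
NULL

#' Zero-lag low-pass filter
#'
#' 4th-order Butterworth applied forward and backward
#' (`signal::filtfilt`), so the output has no phase lag. Stroke rates are
#' well below 1 Hz, so the 6 Hz default preserves the movement content
#' while suppressing sensor noise.
#'
#' @param x numeric signal.
#' @param fs sampling rate, Hz.
#' @param cutoff cutoff frequency, Hz (default 6).
#' @param order filter order (default 4).
#' @return filtered signal, same length.
#' @export
lowpass_filter <- function(x, fs, cutoff = 6, order = 4) {
  stopifnot(cutoff < fs / 2)
  bf <- signal::butter(order, cutoff / (fs / 2), type = "low")
  as.numeric(signal::filtfilt(bf, x))
}

# Local minima of x with prominence >= min_prominence.
# Prominence of a minimum: height to climb from the minimum to reach the
# lowest of the two enclosing higher barriers (standard topographic
# definition, computed on -x as peaks).
find_prominent_minima <- function(x, min_prominence) {
  n <- length(x)
  if (n < 3) return(integer(0))
  cand <- which(diff(sign(diff(x))) > 0) + 1L
  # straightforward O(n * peaks) prominence computation
  prom <- vapply(cand, function(i) {
    lo <- x[i]
    # left barrier: max of x between i and the previous sample lower than lo
    j <- i - 1L
    lbar <- -Inf
    while (j >= 1 && x[j] >= lo) { lbar <- max(lbar, x[j]); j <- j - 1L }
    if (j < 1) lbar <- max(x[1:i])
    # right barrier
    j <- i + 1L
    rbar <- -Inf
    while (j <= n && x[j] >= lo) { rbar <- max(rbar, x[j]); j <- j + 1L }
    if (j > n) rbar <- max(x[i:n])
    min(lbar, rbar) - lo
  }, numeric(1))
  cand[prom >= min_prominence]
}

#' Detect stroke-cycle start events
#'
#' Finds local minima of the (filtered) sagittal knee angle -- maximum
#' knee extension -- with at least `min_prominence` of surrounding
#' flexion and at least `min_period` between events. The first and last
#' samples never become events, so partial leading/trailing cycles are
#' implicitly discarded by [segment_cycles()].
#'
#' @param knee a `joint_angles` object (sagittal knee angle).
#' @param min_prominence minimum prominence in degrees (default 10).
#' @param min_period minimum event spacing in seconds (default 1).
#' @param prefilter low-pass filter before detection (default TRUE).
#' @param window optional `c(t0, t1)` restricting detection, s.
#' @return data frame with columns `t`, `index`, `leg` (class
#'   `stroke_events`).
#' @export
detect_stroke_events <- function(knee, min_prominence = 10, min_period = 1,
                                 prefilter = TRUE, window = NULL) {
  t <- knee$t
  x <- knee$angle
  fs <- 1 / stats::median(diff(t))
  if (prefilter) x <- lowpass_filter(x, fs)
  idx <- find_prominent_minima(x, min_prominence)
  if (!is.null(window))
    idx <- idx[t[idx] >= window[1] & t[idx] <= window[2]]
  # enforce minimum spacing, keeping the deeper minimum of close pairs
  if (length(idx) > 1) {
    keep <- idx[1]
    for (i in idx[-1]) {
      if (t[i] - t[keep[length(keep)]] >= min_period) {
        keep <- c(keep, i)
      } else if (x[i] < x[keep[length(keep)]]) {
        keep[length(keep)] <- i
      }
    }
    idx <- keep
  }
  if (length(idx) < 2)
    stop(sprintf("no strokes detected in %s (%d event(s) found)",
                 knee$joint, length(idx)))
  structure(data.frame(t = t[idx], index = idx, leg = knee$leg),
            class = c("stroke_events", "data.frame"))
}

#' Segment a joint-angle series into raw stroke cycles
#'
#' Cycle k spans the half-open interval `[event_k, event_{k+1})`; with n
#' events there are n - 1 cycles. The sample at the next event is carried
#' along as the interpolation endpoint so normalization preserves the
#' cycle's end value.
#'
#' @param angles a `joint_angles` object.
#' @param events a `stroke_events` data frame (from the same leg's knee).
#' @return list of raw cycles, each `list(t, angle, t_start, t_end)`.
#' @export
segment_cycles <- function(angles, events) {
  if (nrow(events) < 2) stop("need at least 2 events to form a cycle")
  lapply(seq_len(nrow(events) - 1), function(k) {
    t0 <- events$t[k]; t1 <- events$t[k + 1]
    sel <- angles$t >= t0 & angles$t <= t1
    list(t = angles$t[sel], angle = angles$angle[sel],
         t_start = t0, t_end = t1)
  })
}

#' Normalize a raw cycle to 100 points
#'
#' Linear interpolation onto 100 uniformly spaced cycle-percentage points
#' (0 to 100% inclusive); endpoints are preserved exactly. Linear (not
#' spline) interpolation is monotone and cannot overshoot near the sharp
#' propulsion peak.
#'
#' @param cycle a raw cycle from [segment_cycles()].
#' @return numeric vector of exactly 100 angles, with attributes
#'   `t_start`, `t_end`.
#' @export
normalize_cycle <- function(cycle) {
  if (length(cycle$t) < 4) {
    warning("cycle with fewer than 4 samples dropped")
    return(NULL)
  }
  p <- (cycle$t - cycle$t[1]) / (cycle$t[length(cycle$t)] - cycle$t[1])
  grid <- seq(0, 1, length.out = 100)
  out <- stats::approx(p, cycle$angle, xout = grid, ties = "ordered")$y
  attr(out, "t_start") <- cycle$t_start
  attr(out, "t_end") <- cycle$t_end
  out
}

#' Segment and normalize all cycles of a joint-angle series
#'
#' @param angles a `joint_angles` object.
#' @param events `stroke_events` for that leg.
#' @return `n_cycles x 100` matrix (class `normalized_cycles`) with
#'   attributes `joint`, `plane`, `leg`, `t_start`, `t_end`.
#' @export
normalize_cycles <- function(angles, events) {
  raw <- segment_cycles(angles, events)
  cyc <- lapply(raw, normalize_cycle)
  ok <- !vapply(cyc, is.null, logical(1))
  m <- do.call(rbind, cyc[ok])
  structure(m,
            joint = angles$joint, plane = angles$plane, leg = angles$leg,
            t_start = vapply(raw[ok], `[[`, numeric(1), "t_start"),
            t_end = vapply(raw[ok], `[[`, numeric(1), "t_end"),
            class = c("normalized_cycles", "matrix"))
}
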