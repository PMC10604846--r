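#' Gait events and spatiotemporal gait parameters
#'
#' Gait events (heel strikes, toe offs) are detected from coordinates
#' alone: the forward displacement of each ankle relative to the
#' pelvis reaches a local maximum at heel strike (foot furthest ahead)
#' and a local minimum at toe off (foot furthest behind). From the
#' events and the raw sequence, three families of parameters are
#' computed: basic (step length, step-length asymmetry, step width,
#' walking speed), phase-based (stance and swing time per leg) and
#' angle-based (mean/min/max of spine and lower-limb angle signals).
#'
#' @name gait_parameters
NULL

# Local extrema of a 1-D signal with a minimum peak separation.
# Returns indices of strict local maxima of x, greedily pruned so that
# surviving peaks are at least min_sep samples apart (higher peaks win).
.find_peaks <- function(x, min_sep) {
  T_ <- length(x)
  if (T_ < 3L) return(integer(0))
  cand <- which(x[2:(T_ - 1L)] >= x[1:(T_ - 2L)] &
                x[2:(T_ - 1L)] > x[3:T_]) + 1L
  if (length(cand) == 0L) return(integer(0))
  ord <- cand[order(x[cand], decreasing = TRUE)]
  keep <- integer(0)
  for (i in ord) {
    if (all(abs(i - keep) >= min_sep)) keep <- c(keep, i)
  }
  sort(keep)
}

#' Detect heel strikes and toe offs
#'
#' @param seq a `skeleton_sequence` containing at least two full gait
#'   cycles; forward axis is z.
#' @param min_peak_separation minimum time between consecutive events
#'   of the same kind on one side, seconds.
#' @return a `gait_events` list with integer frame-index vectors
#'   `heel_strikes_L`, `heel_strikes_R`, `toe_offs_L`, `toe_offs_R`
#'   (each strictly increasing).
#' @export
detect_gait_events <- function(seq, min_peak_separation = 0.4) {
  stopifnot(inherits(seq, "skeleton_sequence"))
  pelvis_z <- joint_track(seq, "PELVIS")[, 3]
  min_sep <- max(2L, as.integer(round(min_peak_separation * seq$fps)))
  out <- list()
  for (side in c("L", "R")) {
    rel <- joint_track(seq, paste0("ANKLE_", side))[, 3] - pelvis_z
    # sensor noise creates tiny extrema on the flat parts of the cycle;
    # true strikes lie above the signal midline, true toe-offs below
    mid <- mean(range(rel))
    hs <- .find_peaks(rel, min_sep)
    hs <- hs[rel[hs] > mid]
    to <- .find_peaks(-rel, min_sep)
    to <- to[rel[to] < mid]
    if (length(hs) < 2L) {
      stop("insufficient gait cycles: fewer than 2 heel strikes on side ",
           side)
    }
    out[[paste0("heel_strikes_", side)]] <- hs
    out[[paste0("toe_offs_", side)]] <- to
  }
  structure(out, class = "gait_events")
}

#' Basic gait parameters
#'
#' Step length of the striking side is the forward (z) distance
#' between the two ankles at each heel strike; the average step length
#' pools both sides. Asymmetry is the normalized absolute difference
#' 2|L - R| / (L + R) of the side means, which lies in [0, 2] by
#' construction. Step width is the mean lateral ankle separation at
#' heel strikes; walking speed is net pelvis forward displacement over
#' elapsed time.
#'
#' @param seq a `skeleton_sequence`.
#' @param ev a `gait_events` object for `seq`.
#' @return named numeric vector: `avg_step_length` (m),
#'   `step_length_asymmetry`, `step_width` (m), `walking_speed` (m/s).
#' @export
basic_parameters <- function(seq, ev) {
  al <- joint_track(seq, "ANKLE_L")
  ar <- joint_track(seq, "ANKLE_R")
  step_at <- function(frames, lead, trail) {
    abs(lead[frames, 3] - trail[frames, 3])
  }
  steps_L <- step_at(ev$heel_strikes_L, al, ar)
  steps_R <- step_at(ev$heel_strikes_R, ar, al)
  mean_L <- mean(steps_L)
  mean_R <- mean(steps_R)
  widths <- abs(al[c(ev$heel_strikes_L, ev$heel_strikes_R), 1] -
                ar[c(ev$heel_strikes_L, ev$heel_strikes_R), 1])
  pelvis_z <- joint_track(seq, "PELVIS")[, 3]
  elapsed <- if (!is.null(seq$timestamps)) {
    seq$timestamps[length(seq$timestamps)] - seq$timestamps[1]
  } else {
    (n_frames(seq) - 1) / seq$fps
  }
  if (elapsed <= 0) stop("zero elapsed time")
  c(avg_step_length = mean(c(steps_L, steps_R)),
    step_length_asymmetry = if (mean_L + mean_R > 0) {
      2 * abs(mean_L - mean_R) / (mean_L + mean_R)
    } else 0,
    step_width = mean(widths),
    walking_speed = abs(pelvis_z[length(pelvis_z)] - pelvis_z[1]) / elapsed)
}

# Mean interval (frames -> seconds) from each event in `from` to the
# next event in `to`; NA when no pair exists.
.mean_interval <- function(from, to, fps) {
  gaps <- vapply(from, function(f) {
    nxt <- to[to > f]
    if (length(nxt) == 0L) NA_real_ else (nxt[1] - f) / fps
  }, numeric(1))
  gaps <- gaps[!is.na(gaps)]
  if (length(gaps) == 0L) {
    stop("non-alternating events: no valid interval found")
  }
  mean(gaps)
}

#' Phase-based gait parameters
#'
#' Stance time per side is the mean duration from a heel strike to the
#' next toe off on that side; swing time is the mean duration from a
#' toe off to the next heel strike. Per-cycle means, in seconds.
#'
#' @param ev a `gait_events` object.
#' @param fps frames per second the events were detected at.
#' @return named numeric vector: `stance_time_L`, `stance_time_R`,
#'   `swing_time_L`, `swing_time_R` (seconds).
#' @export
phase_parameters <- function(ev, fps) {
  c(stance_time_L = .mean_interval(ev$heel_strikes_L, ev$toe_offs_L, fps),
    stance_time_R = .mean_interval(ev$heel_strikes_R, ev$toe_offs_R, fps),
    swing_time_L = .mean_interval(ev$toe_offs_L, ev$heel_strikes_L, fps),
    swing_time_R = .mean_interval(ev$toe_offs_R, ev$heel_strikes_R, fps))
}

# Trunk deviation from vertical projected onto a plane spanned by the
# vertical axis and one horizontal axis; horiz = 1 (lateral x) gives
# the frontal-plane angle, horiz = 3 (forward z) the sagittal-plane
# ("lateral spine") angle. Degrees, >= 0.
.spine_angle <- function(seq, horiz) {
  v <- joint_track(seq, "HEAD") - joint_track(seq, "PELVIS")
  nrm2 <- rowSums(v[, c(horiz, 2), drop = FALSE]^2)
  bad <- which(nrm2 < .degenerate_eps^2)
  if (length(bad) > 0L) stop("degenerate trunk vector at frame ", bad[1])
  atan2(abs(v[, horiz]), v[, 2]) * .deg
}

#' Angle-based gait parameters
#'
#' Six per-frame angle signals are summarized by their mean, minimum
#' and maximum: frontal spine angle (trunk deviation from vertical in
#' the frontal plane), lateral spine angle (same in the sagittal
#' plane), and the knee and hip bending angles on each side.
#'
#' @param seq a `skeleton_sequence`.
#' @return named numeric vector of 18 values (degrees), ordered
#'   `<signal>_mean`, `<signal>_min`, `<signal>_max` for signals
#'   frontal_spine, lateral_spine, knee_L, knee_R, hip_L, hip_R.
#' @export
angle_based_parameters <- function(seq) {
  cfg <- default_angle_config()
  signals <- list(
    frontal_spine = .spine_angle(seq, 1L),
    lateral_spine = .spine_angle(seq, 3L),
    knee_L = bending_angle(seq, cfg$bending$knee_L),
    knee_R = bending_angle(seq, cfg$bending$knee_R),
    hip_L = bending_angle(seq, cfg$bending$hip_L),
    hip_R = bending_angle(seq, cfg$bending$hip_R)
  )
  out <- numeric(0)
  for (nm in names(signals)) {
    s <- signals[[nm]]
    v <- c(mean(s), min(s), max(s))
    names(v) <- paste0(nm, c("_mean", "_min", "_max"))
    out <- c(out, v)
  }
  out
}

#' Assemble the normalized gait-parameter vector
#'
#' Concatenates the basic, phase-based and angle-based parameters into
#' a fixed-order length-26 vector. Angle-derived entries are divided
#' by 100 so that every entry falls in roughly [0, 2] for
#' physiological gait, matching the scale of the non-angle entries.
#'
#' @param basic output of [basic_parameters()].
#' @param phase output of [phase_parameters()].
#' @param angle_params output of [angle_based_parameters()].
#' @return a named numeric vector of length 26 (class
#'   `gait_parameter_vector`).
#' @export
assemble_parameter_vector <- function(basic, phase, angle_params) {
  v <- c(basic, phase, angle_params / 100)
  bad <- which(!is.finite(v))
  if (length(bad) > 0L) {
    stop("non-finite gait parameter: ", names(v)[bad[1]])
  }
  class(v) <- "gait_parameter_vector"
  v
}

#' Full gait-parameter pipeline for one sequence
#'
#' Convenience wrapper: detects events, computes all three parameter
#' families and assembles the normalized vector.
#'
#' @param seq a `skeleton_sequence`.
#' @param min_peak_separation passed to [detect_gait_events()].
#' @return a `gait_parameter_vector` of length 26.
#' @export
extract_gait_parameters <- function(seq, min_peak_separation = 0.4) {
  ev <- detect_gait_events(seq, min_peak_separation)
  assemble_parameter_vector(
    basic_parameters(seq, ev),
    phase_parameters(ev, seq$fps),
    angle_based_parameters(seq)
  )
}
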