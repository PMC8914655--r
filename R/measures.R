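#' Hand size and range-of-motion measures
#'
#' All size measures are read off the skeleton graph's homogeneous
#' transforms; all motion-range measures scan a [motion_trace()] for the
#' extreme values of per-sample joint angles.  Angles are computed in
#' radians internally and reported in degrees; lengths are millimetres.
#'
#' Side handling: spread angles of left hands are mirrored about the x-axis
#' before extraction so that positive spread points toward the index side on
#' both hands; flexion (a rotation about x) is unaffected by the mirror.
#'
#' @name measures
NULL

#' Length of the segment ending at a frame
#'
#' The Euclidean (L2) norm of the translation part of the frame's
#' child-in-parent transform — the first three entries of its fourth
#' column.  Frames sit at bone begin points (the tip frame at the
#' fingertip), so the edge into a frame spans the bone segment *preceding*
#' it: the edge into `index_proximal` measures the index metacarpal, the
#' edge into `index_tip` measures the index distal phalanx, and the edge
#' into `index_metacarpal` measures the wrist-to-metacarpal-base (carpal)
#' offset.  Use [segment_length()] to query by anatomical bone name.
#'
#' @param graph a [skeleton_graph()].
#' @param bone frame name, e.g. `"index_proximal"`.  The root has no
#'   parent edge and therefore no length.
#' @return length in mm.
#' @export
bone_length <- function(graph, bone) {
  check_frame(graph, bone)
  if (bone == graph$root) {
    stop("the root frame has no parent edge and no bone length",
         call. = FALSE)
  }
  t_ <- transform_translation(graph$edges[[bone]]$transform)
  sqrt(sum(t_^2))
}

# Frame whose incoming edge spans the given anatomical bone.
segment_frame <- function(finger, bone) {
  succ <- c(metacarpal = "proximal", proximal = "intermediate",
            intermediate = "distal", distal = "tip")
  paste(finger, succ[[bone]], sep = "_")
}

#' Length of an anatomical bone
#'
#' @param graph a [skeleton_graph()].
#' @param finger finger name.
#' @param bone one of `"metacarpal"`, `"proximal"`, `"intermediate"`,
#'   `"distal"`.
#' @return length in mm.
#' @export
segment_length <- function(graph, finger, bone) {
  bone <- match.arg(bone, c("metacarpal", "proximal", "intermediate",
                            "distal"))
  bone_length(graph, segment_frame(finger, bone))
}

#' Length of one finger
#'
#' Sum of the bone lengths along the finger chain.  The default bone set is
#' anatomically complete (metacarpal + proximal + intermediate + distal);
#' `mode = "printed"` omits the intermediate phalanx (metacarpal +
#' proximal + distal), matching the bone list of the hand-length formula.
#' The tip frame marks the end of the distal bone and contributes no
#' length of its own.
#'
#' @param graph a [skeleton_graph()].
#' @param finger one of `"thumb"`, `"index"`, `"middle"`, `"ring"`,
#'   `"pinky"`.
#' @param mode `"full"` (default) or `"printed"`.
#' @return length in mm.
#' @export
finger_length <- function(graph, finger, mode = c("full", "printed")) {
  mode <- match.arg(mode)
  finger <- match.arg(finger, HAND_FINGERS)
  bones <- if (mode == "full") {
    c("metacarpal", "proximal", "intermediate", "distal")
  } else {
    c("metacarpal", "proximal", "distal")
  }
  frames <- vapply(bones, function(b) segment_frame(finger, b), character(1))
  missing <- setdiff(frames, graph$nodes)
  if (length(missing) > 0) {
    stop("finger '", finger, "' chain is incomplete: missing ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  sum(vapply(frames, function(f) bone_length(graph, f), numeric(1)))
}

#' Hand length
#'
#' The maximum finger length over index, middle, ring and pinky (the thumb
#' is excluded).  The metacarpal is included in each finger because the
#' tracked hand model folds carpal length into the metacarpal bone.  Ties
#' return the first finger in the fixed order index, middle, ring, pinky.
#'
#' @inheritParams finger_length
#' @return list with `length_mm` and `finger` (the argmax).
#' @export
hand_length <- function(graph, mode = c("full", "printed")) {
  mode <- match.arg(mode)
  fingers <- c("index", "middle", "ring", "pinky")
  lens <- vapply(fingers, function(f) finger_length(graph, f, mode),
                 numeric(1))
  i <- which.max(lens)  # which.max returns the first maximum: the tie rule
  list(length_mm = unname(lens[i]), finger = fingers[i])
}

#' Hand width
#'
#' The absolute value of the first (x) component of the translation of the
#' transform between the pinky-proximal and index-proximal frames.
#'
#' @param graph a [skeleton_graph()].
#' @return width in mm.
#' @export
hand_width <- function(graph) {
  h <- relative_transform(graph, "pinky_proximal", "index_proximal")
  abs(transform_translation(h)[1])
}

# ---- per-sample joint angles ------------------------------------------------

#' Wrist roll angle of one sample
#'
#' The roll component (rotation about x) of the wrist-in-sensor pose.
#'
#' @param sample a [hand_frame_sample()].
#' @return roll angle in degrees.
#' @export
wrist_roll <- function(sample) {
  roll_pitch_yaw(sample$wrist_pose)$roll
}

# Spread angle of one finger: atan2(zx, zz) of the z-column of the
# metacarpal -> proximal transform; left hands mirror x.
finger_spread_angle <- function(sample, finger) {
  h <- relative_transform(sample$graph,
                          frame_id(finger, "metacarpal"),
                          frame_id(finger, "proximal"))
  z <- unclass(h)[1:3, 3]
  zx <- if (sample$side == "left") -z[1] else z[1]
  rad2deg(atan2(zx, z[3]))
}

#' Per-sample finger spread
#'
#' The printed spread formula: fingers are numbered 1 (pinky) to 4 (index),
#' the spread angle of each is `atan2(zx, zz)` of the z-column of its
#' metacarpal-to-proximal transform, and the total is the cumulative sum of
#' adjacent-finger differences
#' `sum_{i=1..3} (theta_{i+1} - theta_i)` — which telescopes to
#' `theta_index - theta_pinky`.  The sum is evaluated term by term.
#'
#' @param sample a [hand_frame_sample()].
#' @return spread in degrees.
#' @export
finger_spread_sample <- function(sample) {
  fingers <- c("pinky", "ring", "middle", "index")  # i = 1..4
  theta <- vapply(fingers, function(f) finger_spread_angle(sample, f),
                  numeric(1))
  sum(theta[2:4] - theta[1:3])
}

# Flexion angle atan2(z_y, z_z) of the z-column of the transform between
# two frames of one finger.
flexion_angle <- function(sample, finger, from_bone, to_bone) {
  h <- relative_transform(sample$graph,
                          frame_id(finger, from_bone),
                          frame_id(finger, to_bone))
  z <- unclass(h)[1:3, 3]
  rad2deg(atan2(z[2], z[3]))
}

#' Per-sample flexion angles of one finger
#'
#' `angle_mp` is the metacarpal-to-proximal flexion, `angle_tip` the
#' proximal-to-fingertip flexion; both are `atan2` of the second and third
#' entries of the z-column of the respective relative transform.
#'
#' @param sample a [hand_frame_sample()].
#' @param finger finger name (default `"index"`).
#' @return list with `angle_mp` and `angle_tip` in degrees.
#' @export
finger_flexion_sample <- function(sample, finger = "index") {
  list(angle_mp = flexion_angle(sample, finger, "metacarpal", "proximal"),
       angle_tip = flexion_angle(sample, finger, "proximal", "tip"))
}

# ---- trace-level ranges -----------------------------------------------------

# Scan a trace with a per-sample extractor, skipping samples whose required
# frames are missing; fail if more than `max_skip_frac` were skipped.
scan_trace <- function(trace, extract, max_skip_frac = 0.5) {
  if (length(trace$samples) == 0) {
    stop("cannot compute a motion range over an empty trace", call. = FALSE)
  }
  values <- list()
  skipped <- 0L
  for (s in trace$samples) {
    v <- tryCatch(extract(s), error = function(e) NULL)
    if (is.null(v)) skipped <- skipped + 1L else values[[length(values) + 1L]] <- v
  }
  if (skipped > max_skip_frac * length(trace$samples)) {
    stop("more than ", round(100 * max_skip_frac),
         "% of samples were missing required frames (", skipped, " of ",
         length(trace$samples), ")", call. = FALSE)
  }
  list(values = values, skipped = skipped)
}

#' Wrist range of motion
#'
#' Collects the extreme wrist-roll values over a trace in a single pass and
#' returns the full motion range `WM = |min RA - max RA|` (the magnitude of
#' the min-minus-max difference), with the extrema and their timestamps.
#'
#' @param trace a [motion_trace()].
#' @param max_skip_frac maximum tolerated fraction of samples missing the
#'   required frames before the measure fails (default 0.5).
#' @return list of class `"range_result"`: `wm_deg`, `min_deg`, `max_deg`,
#'   `min_timestamp_us`, `max_timestamp_us`, `n_skipped`.
#' @export
wrist_motion_range <- function(trace, max_skip_frac = 0.5) {
  if (length(trace$samples) == 0) {
    stop("cannot compute a motion range over an empty trace", call. = FALSE)
  }
  # streaming single pass, constant memory
  lo <- Inf; hi <- -Inf; t_lo <- NA_real_; t_hi <- NA_real_
  skipped <- 0L
  for (s in trace$samples) {
    ra <- tryCatch(wrist_roll(s), error = function(e) NULL)
    if (is.null(ra)) { skipped <- skipped + 1L; next }
    if (ra < lo) { lo <- ra; t_lo <- s$timestamp_us }
    if (ra > hi) { hi <- ra; t_hi <- s$timestamp_us }
  }
  if (skipped > max_skip_frac * length(trace$samples)) {
    stop("more than ", round(100 * max_skip_frac),
         "% of samples were unusable for wrist roll", call. = FALSE)
  }
  structure(list(wm_deg = abs(lo - hi), min_deg = lo, max_deg = hi,
                 min_timestamp_us = t_lo, max_timestamp_us = t_hi,
                 n_skipped = skipped),
            class = "range_result")
}

#' Finger spread of a trace or sample
#'
#' For a single sample, the per-configuration spread
#' ([finger_spread_sample()]).  For a trace, the session value is the
#' maximum per-sample spread (the measured task is the maximum range of
#' finger spread), with the extremum timestamp recorded.
#'
#' @param x a [hand_frame_sample()] or [motion_trace()].
#' @param max_skip_frac see [wrist_motion_range()].
#' @return degrees (sample), or a `"range_result"` list with `fsr_deg`,
#'   `max_timestamp_us`, `n_skipped` (trace).
#' @export
finger_spread <- function(x, max_skip_frac = 0.5) {
  if (inherits(x, "hand_frame_sample")) return(finger_spread_sample(x))
  stopifnot(inherits(x, "motion_trace"))
  scan <- scan_trace(x, function(s) {
    c(finger_spread_sample(s), s$timestamp_us)
  }, max_skip_frac)
  vals <- vapply(scan$values, `[`, numeric(1), 1L)
  ts <- vapply(scan$values, `[`, numeric(1), 2L)
  i <- which.max(vals)
  structure(list(fsr_deg = vals[i], max_timestamp_us = ts[i],
                 n_skipped = scan$skipped),
            class = "range_result")
}

#' Finger flexion range
#'
#' `FF = max(angle_mp) + max(angle_tip)` over the trace: the maxima of the
#' metacarpal-proximal and proximal-fingertip flexion angles are collected
#' independently (they need not occur at the same instant) and summed.
#' The index finger is measured by default.
#'
#' @param trace a [motion_trace()].
#' @param finger finger name (default `"index"`).
#' @param max_skip_frac see [wrist_motion_range()].
#' @return `"range_result"` list: `ff_deg`, `max_angle_mp_deg`,
#'   `max_angle_tip_deg`, their timestamps, `n_skipped`.
#' @export
finger_flexion <- function(trace, finger = "index", max_skip_frac = 0.5) {
  scan <- scan_trace(trace, function(s) {
    a <- finger_flexion_sample(s, finger)
    c(a$angle_mp, a$angle_tip, s$timestamp_us)
  }, max_skip_frac)
  mp <- vapply(scan$values, `[`, numeric(1), 1L)
  tip <- vapply(scan$values, `[`, numeric(1), 2L)
  ts <- vapply(scan$values, `[`, numeric(1), 3L)
  i_mp <- which.max(mp); i_tip <- which.max(tip)
  structure(list(ff_deg = mp[i_mp] + tip[i_tip],
                 max_angle_mp_deg = mp[i_mp],
                 max_angle_tip_deg = tip[i_tip],
                 mp_timestamp_us = ts[i_mp],
                 tip_timestamp_us = ts[i_tip],
                 n_skipped = scan$skipped),
            class = "range_result")
}

#' All size measures of one sample
#'
#' @param sample a [hand_frame_sample()].
#' @param mode finger-length bone set, see [finger_length()].
#' @return list of class `"size_result"`: per-bone lengths, per-finger
#'   lengths, `hand_length_mm`, `hand_length_finger`, `hand_width_mm`.
#' @export
hand_sizes <- function(sample, mode = c("full", "printed")) {
  mode <- match.arg(mode)
  g <- sample$graph
  fingers <- intersect(HAND_FINGERS, unique(sub("_.*$", "", g$nodes)))
  anat <- c("metacarpal", "proximal", "intermediate", "distal")
  bone_lengths <- unlist(lapply(fingers, function(f) {
    v <- vapply(anat, function(b) segment_length(g, f, b), numeric(1))
    names(v) <- paste(f, anat, sep = "_")
    v
  }))
  finger_lengths <- vapply(fingers, function(f) finger_length(g, f, mode),
                           numeric(1))
  hl <- hand_length(g, mode)
  structure(list(bone_lengths_mm = bone_lengths,
                 finger_lengths_mm = finger_lengths,
                 hand_length_mm = hl$length_mm,
                 hand_length_finger = hl$finger,
                 hand_width_mm = hand_width(g)),
            class = "size_result")
}
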