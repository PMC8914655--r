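#' Synthetic hand and motion generation
#'
#' Generates motion traces with known ground truth so every measure and
#' statistic is testable without a tracking device.  A [hand_spec()] fixes
#' rigid bone lengths and metacarpal-base geometry; a [motion_script()]
#' drives smooth joint-angle trajectories (wrist roll, per-finger
#' metacarpophalangeal and interphalangeal flexion, finger spread); a
#' [noise_model()] adds seeded Gaussian position noise on joint points and
#' small-angle orientation noise on bone frames.
#'
#' The ground-truth record is computed from closed-form expressions for
#' every per-sample angle and length, evaluated at the trace's sample
#' times — an independent code path from the transform-graph measures it
#' validates.
#'
#' @name synthetic_hand
NULL

#' Hand specification
#'
#' Default dimensions follow plausible adult anthropometry.  The thumb has
#' a zero-length metacarpal (as the tracked hand model reports it).
#' Metacarpal bases are offset laterally from the wrist (`base_x_mm`,
#' positive toward the thumb side on a right hand) and the metacarpals fan
#' out by fixed abduction angles (`fan_deg`); together with the bone
#' lengths these determine the true hand width.
#'
#' @param bone_lengths_mm 5x4 numeric matrix (rows thumb, index, middle,
#'   ring, pinky; columns metacarpal, proximal, intermediate, distal), mm.
#' @param base_x_mm named numeric, lateral metacarpal-base offsets, mm.
#' @param fan_deg named numeric, fixed metacarpal abduction angles, deg.
#' @param side `"left"` or `"right"`.
#' @return list of class `"hand_spec"`.
#' @export
hand_spec <- function(bone_lengths_mm = default_bone_lengths(),
                      base_x_mm = c(thumb = 30, index = 22, middle = 8,
                                    ring = -8, pinky = -22),
                      fan_deg = c(thumb = 35, index = 6, middle = 0,
                                  ring = -5, pinky = -12),
                      side = c("right", "left")) {
  side <- match.arg(side)
  stopifnot(is.matrix(bone_lengths_mm),
            all(dim(bone_lengths_mm) == c(5L, 4L)),
            all(bone_lengths_mm >= 0),
            setequal(rownames(bone_lengths_mm), HAND_FINGERS),
            setequal(names(base_x_mm), HAND_FINGERS),
            setequal(names(fan_deg), HAND_FINGERS))
  structure(list(bone_lengths_mm = bone_lengths_mm[HAND_FINGERS, ],
                 base_x_mm = base_x_mm[HAND_FINGERS],
                 fan_deg = fan_deg[HAND_FINGERS],
                 side = side),
            class = "hand_spec")
}

#' @rdname hand_spec
#' @export
default_bone_lengths <- function() {
  m <- matrix(c(
    0,  46, 32, 30,   # thumb: zero-length metacarpal
    68, 40, 24, 18,   # index
    64, 45, 27, 18,   # middle
    58, 42, 26, 18,   # ring
    54, 33, 19, 16),  # pinky
    nrow = 5, byrow = TRUE,
    dimnames = list(HAND_FINGERS,
                    c("metacarpal", "proximal", "intermediate", "distal")))
  m
}

#' Motion script
#'
#' Smooth joint-angle trajectories emulating the measurement tasks: active
#' wrist roll (sinusoid of amplitude `roll_amplitude_deg`), maximum finger
#' flexion (raised-cosine ramps 0 -> amplitude -> 0 at the
#' metacarpophalangeal and interphalangeal joints), and maximum finger
#' spread (raised cosine scaled per finger so the total spread peaks at
#' `spread_amplitude_deg`).  Anatomical bounds are enforced: |roll| <= 90,
#' flexion in [0, 110], spread in [0, 40] degrees.
#'
#' @param roll_amplitude_deg wrist roll amplitude (degrees).
#' @param mp_amplitude_deg peak metacarpophalangeal flexion.
#' @param pip_amplitude_deg peak proximal-interphalangeal flexion.
#' @param dip_amplitude_deg peak distal-interphalangeal flexion.
#' @param spread_amplitude_deg peak total finger spread.
#' @param frequency_hz trajectory frequency (default 0.5 Hz).
#' @param duration_s trace duration (default 4 s).
#' @param frame_rate_fps sampling rate (default 60 fps).
#' @return list of class `"motion_script"`.
#' @export
motion_script <- function(roll_amplitude_deg = 0,
                          mp_amplitude_deg = 0,
                          pip_amplitude_deg = 0,
                          dip_amplitude_deg = 0,
                          spread_amplitude_deg = 0,
                          frequency_hz = 0.5,
                          duration_s = 4,
                          frame_rate_fps = 60) {
  if (abs(roll_amplitude_deg) > 90) {
    stop("roll_amplitude_deg exceeds the anatomical bound of 90 degrees",
         call. = FALSE)
  }
  flex_total <- mp_amplitude_deg
  if (mp_amplitude_deg < 0 || pip_amplitude_deg < 0 || dip_amplitude_deg < 0 ||
      mp_amplitude_deg > 110 || pip_amplitude_deg + dip_amplitude_deg > 110) {
    stop("flexion amplitudes must lie within [0, 110] degrees", call. = FALSE)
  }
  if (spread_amplitude_deg < 0 || spread_amplitude_deg > 40) {
    stop("spread_amplitude_deg must lie within [0, 40] degrees",
         call. = FALSE)
  }
  stopifnot(frequency_hz > 0, duration_s > 0, frame_rate_fps > 0)
  structure(list(roll_amplitude_deg = roll_amplitude_deg,
                 mp_amplitude_deg = mp_amplitude_deg,
                 pip_amplitude_deg = pip_amplitude_deg,
                 dip_amplitude_deg = dip_amplitude_deg,
                 spread_amplitude_deg = spread_amplitude_deg,
                 frequency_hz = frequency_hz,
                 duration_s = duration_s,
                 frame_rate_fps = frame_rate_fps),
            class = "motion_script")
}

#' Noise model
#'
#' @param position_sigma_mm Gaussian position noise SD per axis on joint
#'   points (mm).
#' @param orientation_sigma_deg small-angle orientation noise SD composed
#'   onto bone frames (degrees).
#' @return list of class `"noise_model"`.
#' @export
noise_model <- function(position_sigma_mm = 0, orientation_sigma_deg = 0) {
  stopifnot(position_sigma_mm >= 0, orientation_sigma_deg >= 0)
  structure(list(position_sigma_mm = position_sigma_mm,
                 orientation_sigma_deg = orientation_sigma_deg),
            class = "noise_model")
}

# Per-finger spread weights: the scripted total spread sigma(t) is split so
# that theta_index - theta_pinky = sigma(t) exactly.
SPREAD_WEIGHTS <- c(pinky = -0.5, ring = -0.2, middle = 0.1, index = 0.5,
                    thumb = 0)

# raised cosine 0 -> 1 -> 0 over one period
raised_cos <- function(t, freq) 0.5 * (1 - cos(2 * pi * freq * t))

script_angles <- function(script, t) {
  list(roll = script$roll_amplitude_deg * sin(2 * pi * script$frequency_hz * t),
       mp = script$mp_amplitude_deg * raised_cos(t, script$frequency_hz),
       pip = script$pip_amplitude_deg * raised_cos(t, script$frequency_hz),
       dip = script$dip_amplitude_deg * raised_cos(t, script$frequency_hz),
       spread = script$spread_amplitude_deg * raised_cos(t, script$frequency_hz))
}

# Forward kinematics of one sample: world pose of every frame.
# Joint model (right hand; left hands mirror base offsets, fan and spread
# about x): metacarpal frames at the metacarpal base, orientation
# Ry(fan); metacarpophalangeal joint = Ry(spread_f) %*% Rx(-mp);
# interphalangeal joints = Rx(-pip), Rx(-dip); each bone extends along its
# frame's +z axis; the frame named after a bone sits at the bone's begin
# point and the tip frame at the fingertip.
hand_world_poses <- function(spec, wrist_pose, ang) {
  mirror <- if (spec$side == "left") -1 else 1
  wr <- transform_rotation(wrist_pose)
  wt <- transform_translation(wrist_pose)
  world <- list(wrist = wrist_pose)
  for (f in HAND_FINGERS) {
    L <- spec$bone_lengths_mm[f, ]
    base <- c(mirror * spec$base_x_mm[[f]], 0, 0)
    r_meta <- rotation_y(mirror * spec$fan_deg[[f]])
    p_meta <- base
    s_f <- mirror * SPREAD_WEIGHTS[[f]] * ang$spread
    r_mp <- rotation_y(s_f) %*% rotation_x(-ang$mp)
    r_prox <- r_meta %*% r_mp
    p_prox <- p_meta + L[["metacarpal"]] * r_meta[, 3]
    r_int <- r_prox %*% rotation_x(-ang$pip)
    p_int <- p_prox + L[["proximal"]] * r_prox[, 3]
    r_dist <- r_int %*% rotation_x(-ang$dip)
    p_dist <- p_int + L[["intermediate"]] * r_int[, 3]
    p_tip <- p_dist + L[["distal"]] * r_dist[, 3]
    local <- list(metacarpal = list(r_meta, p_meta),
                  proximal = list(r_prox, p_prox),
                  intermediate = list(r_int, p_int),
                  distal = list(r_dist, p_dist),
                  tip = list(r_dist, p_tip))
    for (b in names(local)) {
      world[[paste(f, b, sep = "_")]] <- homogeneous_transform(
        wr %*% local[[b]][[1]], as.numeric(wt + wr %*% local[[b]][[2]]))
    }
  }
  world
}

# orthonormal frame with given z-axis, x chosen from a reference y
frame_from_z <- function(z, y_ref) {
  z <- z / vec_norm(z)
  x <- c(y_ref[2] * z[3] - y_ref[3] * z[2],
         y_ref[3] * z[1] - y_ref[1] * z[3],
         y_ref[1] * z[2] - y_ref[2] * z[1])  # cross(y_ref, z)
  if (vec_norm(x) < 1e-9) x <- c(1, 0, 0)
  x <- x / vec_norm(x)
  y <- c(z[2] * x[3] - z[3] * x[2],
         z[3] * x[1] - z[1] * x[3],
         z[1] * x[2] - z[2] * x[1])  # cross(z, x)
  cbind(x, y, z, deparse.level = 0)
}

small_rotation <- function(sigma_deg) {
  axis <- stats::rnorm(3)
  axis <- axis / vec_norm(axis)
  ang <- deg2rad(stats::rnorm(1, 0, sigma_deg))
  # Rodrigues
  k <- matrix(c(0, -axis[3], axis[2],
                axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(ang) * k + (1 - cos(ang)) * (k %*% k)
}

# Corrupt exact world poses: Gaussian noise on joint points (shared between
# a bone's end and the next bone's begin), then rebuild frame orientations
# from the noisy bone directions and compose small orientation noise.
apply_noise <- function(world, noise) {
  if (noise$position_sigma_mm == 0 && noise$orientation_sigma_deg == 0) {
    return(world)
  }
  noisy <- list(wrist = world$wrist)
  for (f in HAND_FINGERS) {
    frames <- paste(f, HAND_BONES, sep = "_")
    pts <- lapply(frames, function(fr) transform_translation(world[[fr]]))
    names(pts) <- HAND_BONES
    if (noise$position_sigma_mm > 0) {
      pts <- lapply(pts, function(p)
        p + stats::rnorm(3, 0, noise$position_sigma_mm))
    }
    for (i in seq_along(HAND_BONES)) {
      b <- HAND_BONES[i]
      fr <- frames[i]
      r_old <- transform_rotation(world[[fr]])
      if (b == "tip") {
        # the tip is a marker at the distal end carrying the distal bone's
        # orientation (as the trace dialect records it)
        r_new <- transform_rotation(noisy[[frames[i - 1L]]])
      } else {
        seg <- pts[[HAND_BONES[i + 1L]]] - pts[[b]]
        r_new <- if (vec_norm(seg) < 1e-9) r_old else
          frame_from_z(seg, r_old[, 2])
        if (noise$orientation_sigma_deg > 0) {
          r_new <- r_new %*% small_rotation(noise$orientation_sigma_deg)
        }
      }
      noisy[[fr]] <- homogeneous_transform(r_new, pts[[b]])
    }
  }
  noisy
}

#' Generate a synthetic motion trace with ground truth
#'
#' Forward kinematics place every bone frame consistently with the spec
#' lengths and scripted angles; noise is added after posing; the returned
#' ground truth holds closed-form values for every measure.
#'
#' @param spec a [hand_spec()].
#' @param script a [motion_script()].
#' @param noise a [noise_model()].
#' @param seed integer RNG seed; identical seeds reproduce identical
#'   traces.
#' @param wrist_position_mm wrist position in the sensor frame.
#' @return list with `trace` (a [motion_trace()]) and `truth` (see
#'   [ground_truth()]).
#' @export
generate_trace <- function(spec, script = motion_script(),
                           noise = noise_model(), seed = 1,
                           wrist_position_mm = c(0, 150, 0)) {
  stopifnot(inherits(spec, "hand_spec"), inherits(script, "motion_script"),
            inherits(noise, "noise_model"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(as.integer(seed))

  n <- floor(script$duration_s * script$frame_rate_fps) + 1L
  times <- (seq_len(n) - 1L) / script$frame_rate_fps
  samples <- vector("list", n)
  for (i in seq_len(n)) {
    ang <- script_angles(script, times[i])
    wrist_pose <- homogeneous_transform(rotation_x(ang$roll),
                                        wrist_position_mm)
    world <- hand_world_poses(spec, wrist_pose, ang)
    world <- apply_noise(world, noise)
    sk <- skeleton_from_world_poses(world)
    s <- hand_frame_sample(round(times[i] * 1e6), spec$side,
                           sk$wrist_pose, sk$graph)
    s$world_record <- sample_world_record(world)
    samples[[i]] <- s
  }
  trace <- motion_trace(samples, capture_rate = script$frame_rate_fps,
                        device_label = "synthetic")
  list(trace = trace, truth = ground_truth(spec, script, times))
}

# Build the serialization record straight from world poses (canonical and
# byte-stable on rewrite).
sample_world_record <- function(world) {
  wq <- pose_from_transform(world$wrist)
  rec <- list(wrist = list(position_mm = wq$translation,
                           quaternion = wq$quaternion),
              fingers = list())
  for (f in HAND_FINGERS) {
    bones <- vector("list", 4L)
    for (i in seq_len(4L)) {
      b <- BONE_ORDER[i]
      p <- pose_from_transform(world[[paste(f, b, sep = "_")]])
      nxt <- paste(f, HAND_BONES[i + 1L], sep = "_")
      bones[[i]] <- list(bone = b, begin_mm = p$translation,
                         end_mm = transform_translation(world[[nxt]]),
                         quaternion = p$quaternion)
    }
    rec$fingers[[f]] <- list(bones = bones)
  }
  rec
}

#' Analytic ground truth for a scripted synthetic hand
#'
#' Closed-form values of every measure, evaluated independently of the
#' transform-graph machinery.  Range measures are reported both as the
#' analytic extremum of the continuous waveform (`*_analytic`) and as the
#' extremum over the actual sample times (`*_sampled` — what a discrete
#' trace can attain; the two differ by at most one sampling step's angle
#' increment).
#'
#' @param spec a [hand_spec()].
#' @param script a [motion_script()].
#' @param times numeric vector of sample times (s).
#' @return list of ground-truth values (lengths mm, angles deg).
#' @export
ground_truth <- function(spec, script, times) {
  L <- spec$bone_lengths_mm
  full <- rowSums(L)
  printed <- rowSums(L[, c("metacarpal", "proximal", "distal")])
  hl_fingers <- c("index", "middle", "ring", "pinky")
  hl_full <- max(full[hl_fingers])
  hl_printed <- max(printed[hl_fingers])

  # Hand width at the neutral pose: translation between the pinky- and
  # index-proximal frames, expressed in the pinky proximal frame whose
  # rotation is Ry(fan_pinky); mirrored geometry gives the same width.
  mcp <- function(f) {
    c(spec$base_x_mm[[f]], 0, 0) +
      L[f, "metacarpal"] * rotation_y(spec$fan_deg[[f]])[, 3]
  }
  d <- mcp("index") - mcp("pinky")
  fp <- deg2rad(spec$fan_deg[["pinky"]])
  hw <- abs(cos(fp) * d[1] - sin(fp) * d[3])

  ang <- lapply(times, function(t) script_angles(script, t))
  roll <- vapply(ang, `[[`, numeric(1), "roll")
  spread <- vapply(ang, `[[`, numeric(1), "spread")
  mp <- vapply(ang, `[[`, numeric(1), "mp")
  pip <- vapply(ang, `[[`, numeric(1), "pip")
  dip <- vapply(ang, `[[`, numeric(1), "dip")
  # metacarpophalangeal flexion angle as the z-column formula sees it, with
  # the index finger's share of the spread as crosstalk
  s_index <- SPREAD_WEIGHTS[["index"]] * spread
  angle_mp <- rad2deg(atan2(sin(deg2rad(mp)),
                            cos(deg2rad(s_index)) * cos(deg2rad(mp))))
  angle_tip <- pip + dip

  list(
    finger_lengths_full_mm = full,
    finger_lengths_printed_mm = printed,
    hand_length_full_mm = hl_full,
    hand_length_full_finger = hl_fingers[which.max(full[hl_fingers])],
    hand_length_printed_mm = hl_printed,
    hand_width_mm = hw,
    wm_deg_analytic = 2 * abs(script$roll_amplitude_deg),
    wm_deg_sampled = max(roll) - min(roll),
    fsr_deg_analytic = script$spread_amplitude_deg,
    fsr_deg_sampled = max(spread),
    ff_deg_sampled = max(angle_mp) + max(angle_tip),
    ff_deg_analytic = script$mp_amplitude_deg + script$pip_amplitude_deg +
      script$dip_amplitude_deg,
    sample_step_roll_deg = if (length(roll) > 1) max(abs(diff(roll))) else 0
  )
}

#' Batch of simulated measurement sessions
#'
#' Emulates the study's session design: for each participant and each
#' requested hand part, repeated measurements of one part by one device
#' label.  Each repetition regenerates the trace with a fresh seed (derived
#' deterministically from `seed`) and re-measures it, so repetition scatter
#' comes from the noise model.  Participants get slightly different hands
#' (a deterministic per-participant scale factor).
#'
#' @param spec base [hand_spec()].
#' @param script a [motion_script()].
#' @param noise a [noise_model()].
#' @param parts character vector of hand parts to measure; any of
#'   `"hand_length"`, `"hand_width"`, `"index_length"`, `"wrist_range"`,
#'   `"finger_spread"`, `"finger_flexion"`.
#' @param n_repeats repetitions per participant per part (default 15).
#' @param participants number of participants (default 5).
#' @param device device label for the emitted rows.
#' @param seed master seed.
#' @return data.frame in [export_results()] layout.
#' @export
batch_sessions <- function(spec, script = motion_script(),
                           noise = noise_model(),
                           parts = c("hand_length", "hand_width"),
                           n_repeats = 15, participants = 5,
                           device = "synthetic", seed = 1) {
  stopifnot(n_repeats >= 2)
  known <- c("hand_length", "hand_width", "index_length", "wrist_range",
             "finger_spread", "finger_flexion")
  bad <- setdiff(parts, known)
  if (length(bad) > 0) {
    stop("unknown hand part(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  rows <- list()
  for (p in seq_len(participants)) {
    scale <- 1 + 0.04 * (p - (participants + 1) / 2)
    spec_p <- spec
    spec_p$bone_lengths_mm <- spec$bone_lengths_mm * scale
    for (part in parts) {
      for (rep_i in seq_len(n_repeats)) {
        seed_i <- (as.integer(seed) %% 1000L) * 1000000L +
          p * 10000L + match(part, known) * 1000L + rep_i
        g <- generate_trace(spec_p, script, noise, seed = seed_i)
        value <- measure_part(g$trace, part)
        rows[[length(rows) + 1L]] <- data.frame(
          participant = sprintf("P%02d", p), device = device,
          hand_side = spec$side, hand_part = part, repetition = rep_i,
          value = value,
          units = if (part %in% c("wrist_range", "finger_spread",
                                  "finger_flexion")) "deg" else "mm")
      }
    }
  }
  do.call(rbind, rows)
}

# One scalar measure of a trace, by part name.
measure_part <- function(trace, part) {
  switch(part,
    hand_length = hand_length(trace$samples[[1]]$graph)$length_mm,
    hand_width = hand_width(trace$samples[[1]]$graph),
    index_length = finger_length(trace$samples[[1]]$graph, "index"),
    wrist_range = wrist_motion_range(trace)$wm_deg,
    finger_spread = finger_spread(trace)$fsr_deg,
    finger_flexion = finger_flexion(trace)$ff_deg,
    stop("unknown hand part '", part, "'", call. = FALSE))
}
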