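#' Simulated haptic wrist measurement
#'
#' Reproduces the haptic measurement procedure in software: the hand grips
#' an effector at a fixed lever arm from the wrist; a controller ramps up a
#' force applied perpendicular to the wrist-effector vector until the wrist
#' deflection reaches a threshold angle, then holds the force constant until
#' the angle stops changing, waits a hold time, and records the triple
#' (deflection angle, held force, direction).  A forearm holder tilted by a
#' small angle removes the need to pre-bend the wrist; its tilt is carried
#' as configuration metadata.
#'
#' The wrist itself is replaced by a configurable simulated plant — a
#' first-order torsional spring (angle proportional to force) with optional
#' damping lag and flexion/extension asymmetry.  This plant is a synthetic
#' stand-in for a human wrist: it exists so the controller is testable
#' without hardware, and makes no biomechanical claims.
#'
#' Geometry: the wrist sits at `wrist_point`; the effector enters at
#' `effector_entry`.  Vector A is the wrist-to-effector vector in the entry
#' position; as the wrist deflects by an angle the effector swings rigidly
#' on the lever arm within the measurement plane (x-y by default, normal
#' z), giving the current vector; B and C are the vectors at the extreme
#' extension/flexion deflections.  The total deflection angle is the sum of
#' the angles between A and B and between C and A.
#'
#' @name haptic_sim
NULL

#' Haptic session configuration
#'
#' @param threshold_angle_deg target deflection angle in degrees (default
#'   15); must satisfy `0 <= threshold < 90`.
#' @param hold_time_s time the force keeps acting after the angle has
#'   stabilised, before the measurement is saved (default 2 s).
#' @param ramp_rate_n_per_s force ramp slope (default 1 N/s).
#' @param control_step_s controller period (default 0.001 s).
#' @param max_force_n force cap (default 12 N, the device's working-space
#'   maximum; must be `0 < max_force <= 12`).
#' @param speed_limit_mm_per_s effector speed limit enforced by the safety
#'   layer (default 100 mm/s).
#' @param direction `"flexion"` (toward the palm) or `"extension"` (toward
#'   the dorsum).
#' @param holder_tilt_deg forearm-holder tilt to the ground (metadata;
#'   default 3.5 degrees).
#' @param stability_epsilon_deg angle variation below which the deflection
#'   counts as stable (default 0.1 deg).
#' @param stability_window_s window over which stability is assessed
#'   (default 0.5 s).
#' @param plane `"xy"` (default; out-of-plane motion suppressed) or
#'   `"xyz"` — whether deflection angles use planar or full 3-D vectors.
#' @param max_session_s wall-clock simulation budget before the session is
#'   declared unstable (default 60 s).
#' @return list of class `"haptic_config"`.
#' @export
haptic_config <- function(threshold_angle_deg = 15,
                          hold_time_s = 2,
                          ramp_rate_n_per_s = 1,
                          control_step_s = 0.001,
                          max_force_n = 12,
                          speed_limit_mm_per_s = 100,
                          direction = c("flexion", "extension"),
                          holder_tilt_deg = 3.5,
                          stability_epsilon_deg = 0.1,
                          stability_window_s = 0.5,
                          plane = c("xy", "xyz"),
                          max_session_s = 60) {
  direction <- match.arg(direction)
  plane <- match.arg(plane)
  stopifnot(threshold_angle_deg >= 0, threshold_angle_deg < 90,
            max_force_n > 0, max_force_n <= 12,
            ramp_rate_n_per_s > 0, control_step_s > 0,
            hold_time_s >= 0, speed_limit_mm_per_s > 0,
            stability_epsilon_deg > 0, stability_window_s > 0)
  structure(list(threshold_angle_deg = threshold_angle_deg,
                 hold_time_s = hold_time_s,
                 ramp_rate_n_per_s = ramp_rate_n_per_s,
                 control_step_s = control_step_s,
                 max_force_n = max_force_n,
                 speed_limit_mm_per_s = speed_limit_mm_per_s,
                 direction = direction,
                 holder_tilt_deg = holder_tilt_deg,
                 stability_epsilon_deg = stability_epsilon_deg,
                 stability_window_s = stability_window_s,
                 plane = plane,
                 max_session_s = max_session_s),
            class = "haptic_config")
}

#' Simulated wrist plant
#'
#' A torsional spring in force-to-angle form: at steady state the
#' deflection is `force / stiffness` degrees (`gain = 1/stiffness` deg/N).
#' `damping` adds a first-order lag with time constant
#' `damping / stiffness` seconds; zero damping (default) makes the plant
#' quasi-static.  `extension_factor` scales the gain in extension relative
#' to flexion.
#'
#' @param wrist_point 3-vector, wrist position in mm.
#' @param effector_entry 3-vector, effector entry position in mm; the lever
#'   arm `r = |effector_entry - wrist_point|` must be positive.
#' @param stiffness_n_per_deg torsional stiffness (N per degree of
#'   deflection); > 0.
#' @param damping_n_s_per_deg damping (N s per degree); >= 0.
#' @param extension_factor multiplicative gain asymmetry for extension
#'   (default 1, symmetric).
#' @return list of class `"wrist_plant"`.
#' @export
wrist_plant <- function(wrist_point = c(0, 0, 0),
                        effector_entry = c(150, 0, 0),
                        stiffness_n_per_deg = 0.5,
                        damping_n_s_per_deg = 0,
                        extension_factor = 1) {
  wrist_point <- as.numeric(wrist_point)
  effector_entry <- as.numeric(effector_entry)
  r <- sqrt(sum((effector_entry - wrist_point)^2))
  stopifnot(length(wrist_point) == 3L, length(effector_entry) == 3L,
            r > 0, stiffness_n_per_deg > 0, damping_n_s_per_deg >= 0,
            extension_factor > 0)
  structure(list(wrist_point = wrist_point,
                 effector_entry = effector_entry,
                 lever_arm_mm = r,
                 stiffness_n_per_deg = stiffness_n_per_deg,
                 damping_n_s_per_deg = damping_n_s_per_deg,
                 extension_factor = extension_factor),
            class = "wrist_plant")
}

plant_gain <- function(plant, direction) {
  g <- 1 / plant$stiffness_n_per_deg
  if (direction == "extension") g * plant$extension_factor else g
}

# ---- deflection geometry ----------------------------------------------------

vec_norm <- function(v) sqrt(sum(v^2))

project_xy <- function(v) c(v[1], v[2], 0)

#' Angle between deflection vectors
#'
#' The single-sided deflection is the angle between the entry vector A and
#' the current wrist-to-effector vector, from the arccosine of the
#' normalised dot product.  Given both extreme vectors B (extension side)
#' and C (flexion side), the total deflection is
#' `angle(A, B) + angle(C, A)`.
#'
#' @param a entry wrist-to-effector vector (3-vector, nonzero).
#' @param b current or extension-side vector (nonzero).
#' @param c_ optional flexion-side vector; when given, the total two-sided
#'   deflection is returned.
#' @param plane `"xy"` (default, matching the constrained-axis measurement
#'   mode: vectors are projected onto the x-y plane first) or `"xyz"` to
#'   use all three coordinates.
#' @return angle in degrees.
#' @export
deflection_angle <- function(a, b, c_ = NULL, plane = c("xy", "xyz")) {
  plane <- match.arg(plane)
  one <- function(u, v) {
    if (plane == "xy") { u <- project_xy(u); v <- project_xy(v) }
    nu <- vec_norm(u); nv <- vec_norm(v)
    if (nu < 1e-12 || nv < 1e-12) {
      stop("deflection vectors must be nonzero", call. = FALSE)
    }
    rad2deg(acos(max(-1, min(1, sum(u * v) / (nu * nv)))))
  }
  if (is.null(c_)) one(a, b) else one(a, b) + one(c_, a)
}

#' Perpendicular measurement force
#'
#' The applied force is always perpendicular to the current
#' wrist-to-effector vector and lies in the measurement plane, so the full
#' force magnitude acts to deflect the wrist.  For `direction = "flexion"`
#' the force points toward positive plane angle; extension negates it.
#'
#' @param v current wrist-to-effector vector (nonzero).
#' @param direction `"flexion"` or `"extension"`.
#' @param magnitude_n force magnitude in N (>= 0).
#' @return 3-vector force in N, `dot(force, v) = 0`.
#' @export
perpendicular_force <- function(v, direction = c("flexion", "extension"),
                                magnitude_n) {
  direction <- match.arg(direction)
  stopifnot(magnitude_n >= 0)
  u <- project_xy(v)
  if (vec_norm(u) < 1e-12) {
    stop("wrist-to-effector vector must be nonzero in the measurement plane",
         call. = FALSE)
  }
  u <- u / vec_norm(u)
  # in-plane perpendicular: rotate u by +90 deg about the plane normal (z)
  perp <- c(-u[2], u[1], 0)
  s <- if (direction == "extension") -1 else 1
  s * magnitude_n * perp
}

#' Safety speed limiter
#'
#' Clamps a commanded effector velocity to the speed limit, preserving
#' direction.
#'
#' @param velocity 3-vector, mm/s.
#' @param limit_mm_per_s maximum speed.
#' @return clamped velocity, `|v| <= limit`.
#' @export
safety_limiter <- function(velocity, limit_mm_per_s) {
  stopifnot(all(is.finite(velocity)), limit_mm_per_s > 0)
  n <- vec_norm(velocity)
  if (n <= limit_mm_per_s) velocity else velocity * (limit_mm_per_s / n)
}

#' Height-hold corrective force
#'
#' Proportional vertical correction keeping the effector at a set height so
#' the hand does not fall inertly: an effector below the set height gets an
#' upward force, above it a downward one.
#'
#' @param current_height_mm effector height.
#' @param set_height_mm target height.
#' @param gain_n_per_mm proportional gain (default 10 N/mm).
#' @return vertical force component in N (positive = upward).
#' @export
height_hold <- function(current_height_mm, set_height_mm,
                        gain_n_per_mm = 10) {
  gain_n_per_mm * (set_height_mm - current_height_mm)
}

# ---- measurement session ----------------------------------------------------

#' Run one simulated haptic measurement
#'
#' Implements the force-ramp procedure: the force grows by
#' `ramp_rate * control_step` per step while the deflection is below the
#' threshold angle and the force below the cap; after crossing the
#' threshold the force is held constant and keeps acting until the angle
#' varies by less than `stability_epsilon` over `stability_window`; the
#' session then holds for `hold_time` and saves (angle, force, direction).
#' The applied force is perpendicular to the wrist-effector vector at every
#' step, and the effector angular step is clamped so its speed never
#' exceeds the limit.
#'
#' Outcomes: `"completed"` (threshold reached, angle >= threshold and force
#' <= cap); `"force-capped"` (threshold unreachable at the cap: the capped
#' force and the achieved angle are recorded); `"unstable"` (angle never
#' stabilised within the session budget).
#'
#' @param plant a [wrist_plant()].
#' @param config a [haptic_config()].
#' @return list of class `"haptic_result"`: `angle_deg`, `force_n`,
#'   `direction`, `outcome`, the deflection-state vectors `A` and
#'   `current`, and `series` — a data.frame time series with columns
#'   `time_s`, `force_n`, `angle_deg`, `effector_x/y/z_mm`,
#'   `force_x/y/z_n`, `perp_dot` (normalised force-lever dot product) and
#'   `speed_mm_per_s`.
#' @export
run_haptic_measurement <- function(plant, config = haptic_config()) {
  stopifnot(inherits(plant, "wrist_plant"), inherits(config, "haptic_config"))
  dt <- config$control_step_s
  n_max <- ceiling(config$max_session_s / dt)
  sgn <- if (config$direction == "extension") -1 else 1
  gain <- plant_gain(plant, config$direction)
  tau <- plant$damping_n_s_per_deg / plant$stiffness_n_per_deg
  a_vec <- plant$effector_entry - plant$wrist_point
  r_xy <- vec_norm(project_xy(a_vec))
  entry_phase <- atan2(a_vec[2], a_vec[1])
  # largest per-step angle change that keeps the effector at or below the
  # speed limit (degrees; lever arm in the plane)
  max_step_deg <- rad2deg(config$speed_limit_mm_per_s * dt / r_xy)

  force <- 0
  angle <- 0          # signed plane angle magnitude, deg
  held <- FALSE
  hold_steps <- 0L
  window_n <- max(2L, ceiling(config$stability_window_s / dt))
  recent <- rep(NA_real_, window_n)
  outcome <- "unstable"

  times <- force_s <- angle_s <- speed_s <- perp_s <- numeric(n_max)
  eff <- matrix(0, n_max, 3)
  fvec_s <- matrix(0, n_max, 3)

  i <- 0L
  while (i < n_max) {
    i <- i + 1L
    if (!held) {
      if (angle >= config$threshold_angle_deg) {
        held <- TRUE
      } else if (force < config$max_force_n) {
        force <- min(config$max_force_n, force + config$ramp_rate_n_per_s * dt)
      }
    }
    # plant response: first-order lag toward the steady-state deflection
    target <- gain * force
    step <- if (tau > 0) (target - angle) * (1 - exp(-dt / tau)) else
      target - angle
    step <- max(-max_step_deg, min(max_step_deg, step))  # safety clamp
    prev_angle <- angle
    angle <- angle + step

    phase <- entry_phase + sgn * deg2rad(angle)
    current <- c(r_xy * cos(phase), r_xy * sin(phase), a_vec[3])
    fvec <- perpendicular_force(current, config$direction, force)

    times[i] <- i * dt
    force_s[i] <- force
    angle_s[i] <- angle
    eff[i, ] <- plant$wrist_point + current
    fvec_s[i, ] <- fvec
    perp_s[i] <- if (force > 0) {
      abs(sum(fvec * current)) / (vec_norm(fvec) * vec_norm(current))
    } else 0
    speed_s[i] <- r_xy * deg2rad(abs(angle - prev_angle)) / dt

    # termination: stable angle after the threshold was crossed (or after
    # the force cap was reached), then the hold time
    recent <- c(recent[-1], angle)
    stable <- !anyNA(recent) &&
      (max(recent) - min(recent)) < config$stability_epsilon_deg
    at_cap <- force >= config$max_force_n - 1e-12
    if ((held || at_cap) && stable) {
      hold_steps <- hold_steps + 1L
      if (hold_steps * dt >= config$hold_time_s) {
        outcome <- if (held && angle >= config$threshold_angle_deg - 1e-9 &&
                       force <= config$max_force_n) "completed" else
                         "force-capped"
        break
      }
    } else {
      hold_steps <- 0L
    }
  }

  keep <- seq_len(i)
  series <- data.frame(time_s = times[keep], force_n = force_s[keep],
                       angle_deg = angle_s[keep],
                       effector_x_mm = eff[keep, 1],
                       effector_y_mm = eff[keep, 2],
                       effector_z_mm = eff[keep, 3],
                       force_x_n = fvec_s[keep, 1],
                       force_y_n = fvec_s[keep, 2],
                       force_z_n = fvec_s[keep, 3],
                       perp_dot = perp_s[keep],
                       speed_mm_per_s = speed_s[keep])
  structure(list(angle_deg = angle, force_n = force,
                 direction = config$direction, outcome = outcome,
                 threshold_angle_deg = config$threshold_angle_deg,
                 holder_tilt_deg = config$holder_tilt_deg,
                 A = a_vec,
                 current = c(r_xy * cos(entry_phase + sgn * deg2rad(angle)),
                             r_xy * sin(entry_phase + sgn * deg2rad(angle)),
                             a_vec[3]),
                 series = series),
            class = "haptic_result")
}

#' @export
print.haptic_result <- function(x, ...) {
  cat(sprintf("<haptic_result> %s | angle %.2f deg | force %.3f N | %s\n",
              x$direction, x$angle_deg, x$force_n, x$outcome))
  invisible(x)
}
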