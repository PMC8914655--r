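#' Rigid homogeneous transforms
#'
#' A hand skeleton is represented as a graph of coordinate frames, each frame
#' described relative to its parent by a 4x4 homogeneous matrix: a 3x3
#' rotation block `R`, a translation column `t` (millimetres), and a fixed
#' last row `(0, 0, 0, 1)`.  All of the size and angle measures in this
#' package are read off these matrices, so the constructors here validate
#' rigidity strictly.
#'
#' Conventions (fixed for the whole package):
#' * frames are right-handed; positions are in millimetres;
#' * a bone frame's z-axis points from the bone's begin point to its end
#'   point (zero-length bones keep the orientation they were given);
#' * quaternions are scalar-first `(w, x, y, z)`;
#' * matrix indexing is R's native 1-based `[row, column]`, so the z-axis of
#'   a child frame expressed in its parent is the third column
#'   `H[1:3, 3]` and the translation is `H[1:3, 4]`.
#'
#' @name transforms
NULL

#' Construct a homogeneous transform from rotation and translation
#'
#' @param rotation 3x3 rotation matrix (orthonormal, det +1 within 1e-9).
#' @param translation numeric length-3 translation in mm (default zero).
#' @return A 4x4 matrix of class `"hand_transform"`.
#' @export
homogeneous_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  stopifnot(is.matrix(rotation), all(dim(rotation) == c(3L, 3L)),
            is.numeric(translation), length(translation) == 3L)
  h <- diag(4)
  h[1:3, 1:3] <- rotation
  h[1:3, 4] <- translation
  h <- structure(h, class = c("hand_transform", "matrix"))
  validate_transform(h)
  h
}

#' Validate a homogeneous transform
#'
#' Checks the rigidity invariants: orthonormal rotation block with
#' determinant +1 (tolerance 1e-9) and an exact `(0, 0, 0, 1)` last row.
#'
#' @param h 4x4 matrix.
#' @param tol numeric tolerance for orthonormality and the determinant.
#' @return `h`, invisibly; errors if invalid.
#' @export
validate_transform <- function(h, tol = 1e-9) {
  if (!is.matrix(h) || !all(dim(h) == c(4L, 4L)) || !is.numeric(h)) {
    stop("a homogeneous transform must be a numeric 4x4 matrix", call. = FALSE)
  }
  if (!identical(unname(h[4, ]), c(0, 0, 0, 1))) {
    stop("last row of a homogeneous transform must be exactly (0, 0, 0, 1)",
         call. = FALSE)
  }
  r <- h[1:3, 1:3]
  if (max(abs(crossprod(r) - diag(3))) > tol) {
    stop("rotation block is not orthonormal within tolerance ", tol,
         call. = FALSE)
  }
  if (abs(det(r) - 1) > tol) {
    stop("rotation block must have determinant +1 (proper rotation)",
         call. = FALSE)
  }
  invisible(h)
}

#' @export
print.hand_transform <- function(x, ...) {
  cat("<hand_transform>  t = (",
      paste(formatC(x[1:3, 4], format = "fg", digits = 6), collapse = ", "),
      ") mm\n", sep = "")
  print(unclass(x)[1:3, 1:3], ...)
  invisible(x)
}

as_transform <- function(m) {
  structure(m, class = c("hand_transform", "matrix"))
}

#' Rotation block of a transform
#' @param h a homogeneous transform.
#' @return 3x3 rotation matrix.
#' @export
transform_rotation <- function(h) unclass(h)[1:3, 1:3]

#' Translation of a transform
#' @param h a homogeneous transform.
#' @return numeric length-3 translation (mm).
#' @export
transform_translation <- function(h) unclass(h)[1:3, 4]

#' Compose two transforms
#'
#' `compose_transforms(a_H_b, b_H_c)` yields `a_H_c`.
#'
#' @param a,b homogeneous transforms.
#' @return the composed transform.
#' @export
compose_transforms <- function(a, b) {
  as_transform(unclass(a) %*% unclass(b))
}

#' Invert a rigid transform
#'
#' Uses the closed form for rigid motions: `R' = t(R)`, `t' = -t(R) t`.
#'
#' @param h a homogeneous transform.
#' @return the inverse transform.
#' @export
invert_transform <- function(h) {
  r <- transform_rotation(h)
  homogeneous_transform(t(r), -t(r) %*% transform_translation(h))
}

#' Build a transform from a tracked pose
#'
#' Converts an orientation quaternion and a position into a homogeneous
#' transform.  Quaternions are scalar-first `(w, x, y, z)`.  Tracking devices
#' emit slightly denormalised quaternions, so inputs whose norm is within
#' `norm_tol` of 1 are silently renormalised; a (near-)zero quaternion is an
#' error.
#'
#' @param quaternion numeric length-4, scalar-first unit quaternion.
#' @param translation numeric length-3 position in mm.
#' @param norm_tol how far from unit norm a quaternion may stray before it is
#'   rejected (default 1e-6).
#' @return a `hand_transform`.
#' @export
transform_from_pose <- function(quaternion, translation = c(0, 0, 0),
                                norm_tol = 1e-6) {
  stopifnot(is.numeric(quaternion), length(quaternion) == 4L)
  n <- sqrt(sum(quaternion^2))
  if (n < 1e-12) {
    stop("invalid pose: zero quaternion has no orientation", call. = FALSE)
  }
  if (abs(n - 1) > norm_tol) {
    stop("invalid pose: quaternion norm ", format(n),
         " deviates from 1 by more than ", norm_tol, call. = FALSE)
  }
  q <- quaternion / n
  homogeneous_transform(quat_to_rotation(q), translation)
}

# Standard scalar-first quaternion -> rotation matrix conversion.
quat_to_rotation <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

# Shepperd's method: rotation matrix -> scalar-first quaternion, w >= 0.
rotation_to_quat <- function(r) {
  tr <- r[1, 1] + r[2, 2] + r[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s,
           (r[3, 2] - r[2, 3]) / s,
           (r[1, 3] - r[3, 1]) / s,
           (r[2, 1] - r[1, 2]) / s)
  } else if (r[1, 1] > r[2, 2] && r[1, 1] > r[3, 3]) {
    s <- sqrt(1 + r[1, 1] - r[2, 2] - r[3, 3]) * 2
    q <- c((r[3, 2] - r[2, 3]) / s, 0.25 * s,
           (r[1, 2] + r[2, 1]) / s,
           (r[1, 3] + r[3, 1]) / s)
  } else if (r[2, 2] > r[3, 3]) {
    s <- sqrt(1 + r[2, 2] - r[1, 1] - r[3, 3]) * 2
    q <- c((r[1, 3] - r[3, 1]) / s,
           (r[1, 2] + r[2, 1]) / s, 0.25 * s,
           (r[2, 3] + r[3, 2]) / s)
  } else {
    s <- sqrt(1 + r[3, 3] - r[1, 1] - r[2, 2]) * 2
    q <- c((r[2, 1] - r[1, 2]) / s,
           (r[1, 3] + r[3, 1]) / s,
           (r[2, 3] + r[3, 2]) / s, 0.25 * s)
  }
  if (q[1] < 0) q <- -q
  q / sqrt(sum(q^2))
}

#' Extract quaternion and translation from a transform
#'
#' Inverse of [transform_from_pose()]; the returned quaternion has `w >= 0`
#' (quaternions are defined up to sign).
#'
#' @param h a homogeneous transform.
#' @return list with `quaternion` (scalar-first, w >= 0) and `translation`.
#' @export
pose_from_transform <- function(h) {
  validate_transform(h)
  list(quaternion = rotation_to_quat(transform_rotation(h)),
       translation = transform_translation(h))
}

#' Roll, pitch and yaw of a transform
#'
#' Decomposes the rotation block into intrinsic x-y-z Euler angles:
#' `R = Rx(roll) %*% Ry(pitch) %*% Rz(yaw)`, with roll the rotation about
#' the x-axis applied first.  The wrist roll angle used by the wrist
#' range-of-motion measure is the `roll` component of the wrist pose.
#'
#' Extraction formulas (all `atan2`-based, degrees):
#' `pitch = asin(R[1,3])`, `roll = atan2(-R[2,3], R[3,3])`,
#' `yaw = atan2(-R[1,2], R[1,1])`.  At gimbal lock (`|pitch| = 90` degrees
#' within `gimbal_tol`) roll and yaw are not separable; the result carries
#' `gimbal_lock = TRUE`, yaw is set to 0 and roll absorbs the remaining
#' rotation.
#'
#' @param h a homogeneous transform (or bare 4x4/3x3 rotation-bearing matrix).
#' @param gimbal_tol tolerance (on `|cos(pitch)|`) for flagging gimbal lock.
#' @return list with `roll`, `pitch`, `yaw` in degrees and `gimbal_lock`.
#' @export
roll_pitch_yaw <- function(h, gimbal_tol = 1e-9) {
  r <- if (all(dim(h) == c(3L, 3L))) h else unclass(h)[1:3, 1:3]
  sp <- max(-1, min(1, r[1, 3]))
  pitch <- asin(sp)
  if (abs(cos(pitch)) < gimbal_tol) {
    # Rx(roll) Ry(+-90) Rz(yaw) leaves only roll -+ yaw observable; put it
    # all in roll.
    roll <- atan2(sign(sp) * r[2, 1], r[2, 2])
    yaw <- 0
    lock <- TRUE
  } else {
    roll <- atan2(-r[2, 3], r[3, 3])
    yaw <- atan2(-r[1, 2], r[1, 1])
    lock <- FALSE
  }
  list(roll = rad2deg(roll), pitch = rad2deg(pitch), yaw = rad2deg(yaw),
       gimbal_lock = lock)
}

#' Elementary rotations (degrees)
#'
#' Right-handed rotations about the coordinate axes, used to build scripted
#' poses and to reconstruct rotations from roll/pitch/yaw triples.
#'
#' @param angle_deg rotation angle in degrees.
#' @return 3x3 rotation matrix.
#' @export
rotation_x <- function(angle_deg) {
  a <- deg2rad(angle_deg); c_ <- cos(a); s <- sin(a)
  matrix(c(1, 0, 0, 0, c_, -s, 0, s, c_), 3, 3, byrow = TRUE)
}

#' @rdname rotation_x
#' @export
rotation_y <- function(angle_deg) {
  a <- deg2rad(angle_deg); c_ <- cos(a); s <- sin(a)
  matrix(c(c_, 0, s, 0, 1, 0, -s, 0, c_), 3, 3, byrow = TRUE)
}

#' @rdname rotation_x
#' @export
rotation_z <- function(angle_deg) {
  a <- deg2rad(angle_deg); c_ <- cos(a); s <- sin(a)
  matrix(c(c_, -s, 0, s, c_, 0, 0, 0, 1), 3, 3, byrow = TRUE)
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi
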