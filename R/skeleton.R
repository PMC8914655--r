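#' Hand skeleton frame graph
#'
#' The tracked hand is modelled as a rooted tree of named coordinate frames:
#' the wrist at the root, and for each finger a chain
#' wrist -> metacarpal -> proximal -> intermediate -> distal -> tip.
#' Each edge carries the child frame expressed in its parent as a
#' homogeneous transform, so any transform inside the hand can be retrieved
#' by composing along the unique tree path.
#'
#' Frame names use the fixed vocabulary `"<finger>_<bone>"` with fingers
#' `thumb, index, middle, ring, pinky` and bones
#' `metacarpal, proximal, intermediate, distal, tip`; the root is `"wrist"`.
#' The tracked hand model reports a zero-length thumb metacarpal: zero-length
#' bones are legal (their direction is taken from the frame orientation).
#'
#' @name skeleton
NULL

HAND_FINGERS <- c("thumb", "index", "middle", "ring", "pinky")
HAND_BONES <- c("metacarpal", "proximal", "intermediate", "distal", "tip")

#' Frame identifier
#'
#' @param finger one of `"thumb"`, `"index"`, `"middle"`, `"ring"`,
#'   `"pinky"`, or `"wrist"` for the root (which carries no bone label).
#' @param bone one of `"metacarpal"`, `"proximal"`, `"intermediate"`,
#'   `"distal"`, `"tip"`; ignored for the wrist.
#' @return frame name string, e.g. `"index_proximal"`.
#' @export
frame_id <- function(finger, bone = NULL) {
  if (identical(finger, "wrist") || identical(finger, "root")) return("wrist")
  finger <- match.arg(finger, HAND_FINGERS)
  bone <- match.arg(bone, HAND_BONES)
  paste(finger, bone, sep = "_")
}

#' All frame names of a complete hand
#' @return character vector: `"wrist"` plus 25 finger-bone frames.
#' @export
hand_frame_vocabulary <- function() {
  c("wrist", as.vector(outer(HAND_FINGERS, HAND_BONES, paste, sep = "_")))
}

#' Construct a skeleton graph
#'
#' @param edges named list: `edges[[child]]` is a list with elements
#'   `parent` (frame name) and `transform` (child-in-parent
#'   [homogeneous_transform()]).
#' @param root root frame name (default `"wrist"`).
#' @return object of class `"skeleton_graph"`.
#' @export
skeleton_graph <- function(edges, root = "wrist") {
  children <- names(edges)
  stopifnot(!is.null(children), !anyDuplicated(children))
  nodes <- union(root, children)
  for (child in children) {
    e <- edges[[child]]
    if (!e$parent %in% nodes) {
      stop("edge parent '", e$parent, "' is not a node of the graph",
           call. = FALSE)
    }
    validate_transform(e$transform)
  }
  if (root %in% children) {
    stop("root frame '", root, "' must not have a parent", call. = FALSE)
  }
  g <- structure(list(root = root, edges = edges, nodes = nodes),
                 class = "skeleton_graph")
  # tree check: every non-root node reaches the root without cycles
  for (n in nodes) frame_path_to_root(g, n)
  g
}

#' @export
print.skeleton_graph <- function(x, ...) {
  cat("<skeleton_graph> root =", x$root, "|", length(x$nodes), "frames\n")
  invisible(x)
}

#' @export
format.skeleton_graph <- function(x, ...) {
  paste0("skeleton_graph(", length(x$nodes), " frames)")
}

frame_parent <- function(graph, frame) {
  if (frame == graph$root) return(NA_character_)
  graph$edges[[frame]]$parent
}

frame_path_to_root <- function(graph, frame) {
  path <- character()
  n <- frame
  while (n != graph$root) {
    if (n %in% path) stop("cycle detected at frame '", n, "'", call. = FALSE)
    path <- c(path, n)
    e <- graph$edges[[n]]
    if (is.null(e)) {
      stop("frame '", n, "' is disconnected from the root", call. = FALSE)
    }
    n <- e$parent
  }
  path
}

check_frame <- function(graph, frame) {
  if (!frame %in% graph$nodes) {
    stop("unknown frame '", frame, "' in skeleton graph", call. = FALSE)
  }
}

# Pose of `frame` expressed in the root, composed leaf-upward.
frame_in_root <- function(graph, frame) {
  h <- diag(4)
  n <- frame
  while (n != graph$root) {
    e <- graph$edges[[n]]
    h <- unclass(e$transform) %*% h
    n <- e$parent
  }
  as_transform(h)
}

#' Relative transform between two frames
#'
#' Returns the pose of `target` expressed in `source`, composed along the
#' unique tree path between them:
#' `source_H_target = inv(root_H_source) %*% root_H_target`.
#'
#' @param graph a [skeleton_graph()].
#' @param source,target frame names.
#' @return a `hand_transform`.
#' @export
relative_transform <- function(graph, source, target) {
  check_frame(graph, source)
  check_frame(graph, target)
  if (source == target) return(as_transform(diag(4)))
  hs <- frame_in_root(graph, source)
  ht <- frame_in_root(graph, target)
  compose_transforms(invert_transform(hs), ht)
}

#' Canonical parent of a frame in the hand tree
#'
#' @param frame a frame name from [hand_frame_vocabulary()].
#' @return the parent frame name (`NA` for the wrist root).
#' @export
canonical_parent <- function(frame) {
  if (frame == "wrist") return(NA_character_)
  parts <- strsplit(frame, "_", fixed = TRUE)[[1]]
  finger <- parts[1]; bone <- parts[2]
  idx <- match(bone, HAND_BONES)
  if (is.na(idx)) stop("unknown bone '", bone, "'", call. = FALSE)
  if (idx == 1L) "wrist" else paste(finger, HAND_BONES[idx - 1L], sep = "_")
}

#' Build a skeleton graph from world-frame poses
#'
#' Takes the pose of every frame expressed in one common (sensor/world)
#' frame and derives the child-in-parent edge transforms of the canonical
#' hand tree: `parent_H_child = inv(world_H_parent) %*% world_H_child`.
#' The wrist pose itself is returned alongside so callers can keep the
#' sensor-frame reference.
#'
#' @param world_poses named list of `hand_transform` world poses; must
#'   contain `"wrist"` and any subset of finger-bone frames forming
#'   complete prefixes of each chain.
#' @return list with `graph` (a [skeleton_graph()]) and `wrist_pose`.
#' @export
skeleton_from_world_poses <- function(world_poses) {
  if (!"wrist" %in% names(world_poses)) {
    stop("world poses must include the 'wrist' frame", call. = FALSE)
  }
  edges <- list()
  for (frame in setdiff(names(world_poses), "wrist")) {
    parent <- canonical_parent(frame)
    if (!parent %in% names(world_poses)) {
      stop("frame '", frame, "' present without its parent '", parent, "'",
           call. = FALSE)
    }
    edges[[frame]] <- list(
      parent = parent,
      transform = compose_transforms(invert_transform(world_poses[[parent]]),
                                     world_poses[[frame]])
    )
  }
  list(graph = skeleton_graph(edges), wrist_pose = world_poses[["wrist"]])
}

#' One tracked hand frame
#'
#' A single decoded tracking sample: a timestamp, the hand side, the wrist
#' pose in the sensor frame, and the skeleton graph of child-in-parent
#' transforms rooted at the wrist.
#'
#' @param timestamp_us capture timestamp in microseconds (finite, >= 0).
#' @param side `"left"` or `"right"`.
#' @param wrist_pose wrist-in-sensor `hand_transform`.
#' @param graph a [skeleton_graph()] rooted at `"wrist"`.
#' @return object of class `"hand_frame_sample"`.
#' @export
hand_frame_sample <- function(timestamp_us, side, wrist_pose, graph) {
  stopifnot(is.numeric(timestamp_us), length(timestamp_us) == 1L,
            is.finite(timestamp_us), timestamp_us >= 0)
  timestamp_us <- as.numeric(timestamp_us)
  side <- match.arg(side, c("left", "right"))
  validate_transform(wrist_pose)
  stopifnot(inherits(graph, "skeleton_graph"))
  structure(list(timestamp_us = timestamp_us, side = side,
                 wrist_pose = wrist_pose, graph = graph),
            class = "hand_frame_sample")
}

#' A time-ordered motion trace
#'
#' @param samples list of [hand_frame_sample()] objects with non-decreasing
#'   timestamps, all of one hand side.
#' @param capture_rate frames per second (metadata).
#' @param device_label free-text device description (metadata).
#' @return object of class `"motion_trace"`.
#' @export
motion_trace <- function(samples = list(), capture_rate = 60,
                         device_label = "synthetic") {
  if (length(samples) > 0) {
    ts <- vapply(samples, function(s) s$timestamp_us, numeric(1))
    if (any(diff(ts) < 0)) {
      stop("motion trace timestamps must be non-decreasing", call. = FALSE)
    }
    sides <- unique(vapply(samples, function(s) s$side, character(1)))
    if (length(sides) > 1) {
      stop("all samples in a motion trace must share one hand side",
           call. = FALSE)
    }
  }
  structure(list(samples = samples, capture_rate = capture_rate,
                 device_label = device_label),
            class = "motion_trace")
}

#' @export
print.motion_trace <- function(x, ...) {
  n <- length(x$samples)
  cat("<motion_trace>", n, "frames")
  if (n > 0) {
    dur <- (x$samples[[n]]$timestamp_us - x$samples[[1]]$timestamp_us) / 1e6
    cat(sprintf(" | %s hand | %.2f s @ %g fps",
                x$samples[[1]]$side, dur, x$capture_rate))
  }
  cat("\n")
  invisible(x)
}

#' @export
length.motion_trace <- function(x) length(x$samples)

#' Apply a global rigid transform to every sample of a trace
#'
#' Moves the whole hand rigidly in the sensor frame (only the wrist pose
#' changes; child-in-parent transforms are untouched).  Useful for testing
#' rigid-motion invariance of the size measures.
#'
#' @param trace a [motion_trace()].
#' @param transform a `hand_transform` applied on the left of every wrist
#'   pose.
#' @return the transformed trace.
#' @export
transform_trace <- function(trace, transform) {
  validate_transform(transform)
  trace$samples <- lapply(trace$samples, function(s) {
    s$wrist_pose <- compose_transforms(transform, s$wrist_pose)
    s
  })
  trace
}
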