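# Independent brute-force oracles and random-case builders.  These share no
# code path with the implementations they check.

random_unit_quat <- function() {
  q <- stats::rnorm(4)
  q / sqrt(sum(q^2))
}

# Quaternion -> rotation via the outer-product identity
# R = (w^2 - |v|^2) I + 2 v v' + 2 w [v]_x  (distinct from the element-wise
# formula used by the package).
oracle_quat_to_mat <- function(q) {
  w <- q[1]; v <- q[2:4]
  vx <- matrix(c(0, -v[3], v[2],
                 v[3], 0, -v[1],
                 -v[2], v[1], 0), 3, 3, byrow = TRUE)
  (w^2 - sum(v^2)) * diag(3) + 2 * tcrossprod(v) + 2 * w * vx
}

random_rotation <- function() oracle_quat_to_mat(random_unit_quat())

random_transform <- function(scale = 100) {
  homogeneous_transform(random_rotation(), stats::rnorm(3, 0, scale))
}

# A random rooted tree with `n` nodes named f1..fn (f1 the root) and random
# rigid edges; parents drawn uniformly among earlier nodes.
random_tree_graph <- function(n) {
  nodes <- paste0("f", seq_len(n))
  edges <- list()
  for (i in 2:n) {
    edges[[nodes[i]]] <- list(parent = nodes[sample.int(i - 1L, 1L)],
                              transform = random_transform())
  }
  skeleton_graph(edges, root = nodes[1])
}

# Brute-force relative transform: walk both frames' ancestor chains to the
# root, build explicit 4x4 path products, and combine with solve().
oracle_relative <- function(graph, source, target) {
  chain <- function(f) {
    h <- diag(4)
    while (f != graph$root) {
      e <- graph$edges[[f]]
      h <- unclass(e$transform) %*% h
      f <- e$parent
    }
    h
  }
  solve(chain(source)) %*% chain(target)
}

# World poses of a hand where only the wrist and per-finger
# metacarpal/proximal frames exist, with the given rotations; enough for
# spread-angle checks.
spread_world_poses <- function(meta_rots, prox_rots) {
  world <- list(wrist = homogeneous_transform())
  for (f in names(meta_rots)) {
    world[[paste0(f, "_metacarpal")]] <-
      homogeneous_transform(meta_rots[[f]], stats::rnorm(3, 0, 30))
    world[[paste0(f, "_proximal")]] <-
      homogeneous_transform(prox_rots[[f]], stats::rnorm(3, 0, 30))
  }
  world
}

# Build a hand_frame_sample with arbitrary per-frame world poses.
sample_from_world <- function(world, timestamp_us = 0, side = "right") {
  sk <- skeleton_from_world_poses(world)
  hand_frame_sample(timestamp_us, side, sk$wrist_pose, sk$graph)
}

# A complete neutral-pose right hand as world poses, bones along +z.
neutral_world_poses <- function(lengths = c(60, 35, 20, 15), base = 20) {
  world <- list(wrist = homogeneous_transform())
  for (f in c("thumb", "index", "middle", "ring", "pinky")) {
    x0 <- base * (match(f, c("thumb", "index", "middle", "ring", "pinky")) - 3)
    z <- 0
    for (i in seq_along(c("metacarpal", "proximal", "intermediate", "distal"))) {
      b <- c("metacarpal", "proximal", "intermediate", "distal")[i]
      world[[paste0(f, "_", b)]] <-
        homogeneous_transform(diag(3), c(x0, 0, z))
      z <- z + lengths[i]
    }
    world[[paste0(f, "_tip")]] <- homogeneous_transform(diag(3), c(x0, 0, z))
  }
  world
}
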