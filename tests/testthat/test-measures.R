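make_neutral_sample <- function(lengths = c(60, 35, 20, 15)) {
  sample_from_world(neutral_world_poses(lengths))
}

test_that("bone length is the L2 norm of the edge translation", {
  edges <- list(index_metacarpal = list(
    parent = "wrist",
    transform = homogeneous_transform(diag(3), c(3, 4, 0))))
  g <- skeleton_graph(edges)
  expect_equal(bone_length(g, "index_metacarpal"), 5)

  edges$index_metacarpal$transform <- homogeneous_transform()
  g <- skeleton_graph(edges)
  expect_equal(bone_length(g, "index_metacarpal"), 0)  # zero-length bone

  expect_error(bone_length(g, "wrist"), "root")

  set.seed(31)
  for (i in 1:100) {
    t_ <- stats::rnorm(3, 0, 40)
    g <- skeleton_graph(list(index_metacarpal = list(
      parent = "wrist",
      transform = homogeneous_transform(random_rotation(), t_))))
    # independent scalar computation
    expect_lt(abs(bone_length(g, "index_metacarpal") -
                    sqrt(t_[1]^2 + t_[2]^2 + t_[3]^2)), 1e-9)
  }
})

test_that("finger length sums the configured bone set", {
  s <- make_neutral_sample(c(60, 35, 20, 15))
  expect_equal(finger_length(s$graph, "index"), 130)
  expect_equal(finger_length(s$graph, "index", mode = "printed"), 110)

  set.seed(32)
  for (i in 1:20) {
    lens <- stats::runif(4, 5, 70)
    g <- make_neutral_sample(lens)$graph
    expect_equal(finger_length(g, "middle"), sum(lens), tolerance = 1e-9)
    expect_equal(finger_length(g, "middle", "printed"), sum(lens[-3]),
                 tolerance = 1e-9)
  }

  g <- skeleton_graph(list(index_metacarpal = list(
    parent = "wrist", transform = homogeneous_transform())))
  expect_error(finger_length(g, "index"), "incomplete")
})

test_that("hand length is the maximum non-thumb finger length with a fixed tie order", {
  spec <- hand_spec()
  tr <- generate_trace(spec, motion_script(duration_s = 0.05), seed = 1)$trace
  hl <- hand_length(tr$samples[[1]]$graph)
  lens <- vapply(c("index", "middle", "ring", "pinky"),
                 function(f) finger_length(tr$samples[[1]]$graph, f),
                 numeric(1))
  expect_equal(hl$length_mm, max(lens))
  expect_identical(hl$finger, "middle")

  # equal chains: first of index, middle, ring, pinky wins
  g <- make_neutral_sample()$graph
  tie <- hand_length(g)
  expect_identical(tie$finger, "index")
  expect_equal(tie$length_mm, 130)
})

test_that("hand width is |x| of the pinky-to-index proximal translation", {
  g <- make_neutral_sample()$graph  # bases 20 mm apart, fingers parallel
  expect_equal(hand_width(g), 60)   # pinky at +2*20 of index... |(-20)-40|

  set.seed(33)
  for (i in 1:20) {
    world <- neutral_world_poses(base = stats::runif(1, 5, 30))
    g <- sample_from_world(world)$graph
    oracle <- abs(oracle_relative(g, "pinky_proximal",
                                  "index_proximal")[1, 4])
    expect_lt(abs(hand_width(g) - oracle), 1e-9)
  }
})

test_that("wrist motion range collects roll extremes", {
  world <- neutral_world_poses()
  sk <- skeleton_from_world_poses(world)
  rolled <- function(ts, deg) {
    wp <- homogeneous_transform(rotation_x(deg), c(0, 0, 0))
    hand_frame_sample(ts, "right", wp, sk$graph)
  }
  tr <- motion_trace(list(rolled(0, 10), rolled(1, -60), rolled(2, 70),
                          rolled(3, 0)))
  wm <- wrist_motion_range(tr)
  expect_equal(wm$wm_deg, 130)
  expect_equal(wm$min_deg, -60)
  expect_equal(wm$max_deg, 70)
  expect_equal(wm$min_timestamp_us, 1)

  const <- motion_trace(list(rolled(0, 15), rolled(1, 15)))
  expect_equal(wrist_motion_range(const)$wm_deg, 0)
  expect_error(wrist_motion_range(motion_trace()), "empty")
})

test_that("a sampled sinusoidal roll recovers twice its amplitude", {
  g <- generate_trace(hand_spec(), motion_script(roll_amplitude_deg = 45),
                      seed = 2)
  wm <- wrist_motion_range(g$trace)
  step <- g$truth$sample_step_roll_deg
  expect_lt(abs(wm$wm_deg - 90), step + 1e-9)
})

test_that("finger spread telescopes to index minus pinky", {
  # all z-axes parallel: zero spread
  s <- make_neutral_sample()
  expect_equal(finger_spread_sample(s), 0)

  # pinky at -20, index at +25, middle/ring arbitrary
  rots <- list(pinky = rotation_y(-20), ring = rotation_y(7),
               middle = rotation_y(-3), index = rotation_y(25))
  world <- spread_world_poses(
    meta_rots = lapply(rots, function(x) diag(3)), prox_rots = rots)
  expect_equal(finger_spread_sample(sample_from_world(world)), 45,
               tolerance = 1e-9)

  # random configurations: term-by-term printed sum vs telescoped ends
  set.seed(34)
  for (i in 1:100) {
    prox <- lapply(setNames(nm = c("pinky", "ring", "middle", "index")),
                   function(f) random_rotation())
    meta <- lapply(prox, function(x) random_rotation())
    smp <- sample_from_world(spread_world_poses(meta, prox))
    theta <- vapply(c("pinky", "ring", "middle", "index"), function(f) {
      m <- oracle_relative(smp$graph, paste0(f, "_metacarpal"),
                           paste0(f, "_proximal"))
      atan2(m[1, 3], m[3, 3]) * 180 / pi
    }, numeric(1))
    printed_sum <- (theta[2] - theta[1]) + (theta[3] - theta[2]) +
      (theta[4] - theta[3])
    expect_equal(finger_spread_sample(smp), unname(printed_sum),
                 tolerance = 1e-9)
    expect_equal(unname(printed_sum), unname(theta[4] - theta[1]),
                 tolerance = 1e-9)
  }
})

test_that("finger flexion sums the two independent angle maxima", {
  spec <- hand_spec()
  script <- motion_script(mp_amplitude_deg = 50, pip_amplitude_deg = 45,
                          dip_amplitude_deg = 25)
  g <- generate_trace(spec, script, seed = 3)
  ff <- finger_flexion(g$trace)
  expect_equal(ff$ff_deg, g$truth$ff_deg_sampled, tolerance = 1e-9)
  expect_equal(ff$max_angle_tip_deg, 70, tolerance = 1e-9)

  # motionless straight finger
  static <- generate_trace(spec, motion_script(duration_s = 0.05), seed = 4)
  expect_equal(finger_flexion(static$trace)$ff_deg, 0, tolerance = 1e-9)

  # brute-force per-sample scan over both angles
  mp <- vapply(g$trace$samples,
               function(s) finger_flexion_sample(s)$angle_mp, numeric(1))
  tip <- vapply(g$trace$samples,
                function(s) finger_flexion_sample(s)$angle_tip, numeric(1))
  expect_equal(ff$ff_deg, max(mp) + max(tip), tolerance = 1e-12)
})

test_that("range measures are monotone as the trace is extended", {
  g <- generate_trace(hand_spec(),
                      motion_script(roll_amplitude_deg = 40,
                                    mp_amplitude_deg = 45,
                                    pip_amplitude_deg = 30),
                      seed = 5)
  tr <- g$trace
  cuts <- c(20, 60, 120, length(tr))
  wm_prev <- -Inf; ff_prev <- -Inf
  for (k in cuts) {
    sub <- motion_trace(tr$samples[1:k], tr$capture_rate, tr$device_label)
    wm <- wrist_motion_range(sub)$wm_deg
    ff <- finger_flexion(sub)$ff_deg
    expect_gte(wm, wm_prev)
    expect_gte(ff, ff_prev)
    wm_prev <- wm; ff_prev <- ff
  }
})

test_that("size measures are invariant under a global rigid motion", {
  set.seed(35)
  g <- generate_trace(hand_spec(), motion_script(duration_s = 0.05),
                      seed = 6)$trace
  s <- g$samples[[1]]
  world <- list(wrist = s$wrist_pose)
  for (f in setdiff(s$graph$nodes, "wrist")) {
    world[[f]] <- compose_transforms(s$wrist_pose,
                                     relative_transform(s$graph, "wrist", f))
  }
  motion <- random_transform()
  moved <- lapply(world, function(h) compose_transforms(motion, h))
  s2 <- sample_from_world(moved)
  z1 <- hand_sizes(s); z2 <- hand_sizes(s2)
  expect_equal(z2$hand_length_mm, z1$hand_length_mm, tolerance = 1e-9)
  expect_equal(z2$hand_width_mm, z1$hand_width_mm, tolerance = 1e-9)
  expect_equal(z2$bone_lengths_mm, z1$bone_lengths_mm, tolerance = 1e-9)
})

test_that("bone-length scatter grows with position noise and vanishes without it", {
  sds <- vapply(c(0, 0.5, 1, 2), function(sig) {
    tr <- generate_trace(hand_spec(),
                         motion_script(duration_s = 5, frame_rate_fps = 60),
                         noise_model(position_sigma_mm = sig), seed = 40)$trace
    stats::sd(vapply(tr$samples,
                     function(s) segment_length(s$graph, "index", "proximal"),
                     numeric(1)))
  }, numeric(1))
  expect_equal(sds[1], 0)
  expect_true(all(diff(sds) > 0))
})

test_that("dropout-heavy traces fail loudly, sparse dropouts are counted", {
  g <- generate_trace(hand_spec(), motion_script(roll_amplitude_deg = 30,
                                                 duration_s = 1),
                      seed = 7)$trace
  # cripple the index chain in some samples
  cripple <- function(s) {
    s$graph$nodes <- setdiff(s$graph$nodes, "index_tip")
    s$graph$edges[["index_tip"]] <- NULL
    s
  }
  half <- g
  half$samples[1:20] <- lapply(half$samples[1:20], cripple)
  ff <- finger_flexion(half)
  expect_equal(ff$n_skipped, 20L)
  most <- g
  most$samples[1:50] <- lapply(most$samples[1:50], cripple)
  expect_error(finger_flexion(most), "skip|missing required frames")
})
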