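test_that("deflection angles match the arccos dot-product geometry", {
  a <- c(1, 0, 0)
  b <- c(cos(pi / 6), sin(pi / 6), 0)   # 30 deg from a
  c_ <- c(cos(pi / 9), -sin(pi / 9), 0) # 20 deg on the other side
  expect_equal(deflection_angle(a, b, c_), 50, tolerance = 1e-9)
  expect_equal(deflection_angle(a, a, a), 0)
  expect_error(deflection_angle(a, c(0, 0, 0)), "nonzero")

  set.seed(51)
  for (i in 1:500) {
    u <- stats::rnorm(3); v <- stats::rnorm(3)
    got <- deflection_angle(u, v, plane = "xyz")
    oracle <- acos(max(-1, min(1, sum(u * v) /
                                 sqrt(sum(u^2) * sum(v^2))))) * 180 / pi
    expect_lt(abs(got - oracle), 1e-9)
  }
})

test_that("planar mode measures angles after projecting out z", {
  a <- c(1, 0, 5)
  b <- c(0, 1, -2)
  expect_equal(deflection_angle(a, b, plane = "xy"), 90, tolerance = 1e-9)
})

test_that("the applied force is perpendicular, in-plane and direction-signed", {
  set.seed(52)
  for (i in 1:50) {
    v <- c(stats::rnorm(2, 0, 100), stats::rnorm(1, 0, 10))
    f <- perpendicular_force(v, "flexion", 5)
    expect_lt(abs(sum(f * v)), 1e-9)
    expect_equal(sqrt(sum(f^2)), 5, tolerance = 1e-12)
    expect_equal(f[3], 0)  # in the measurement plane
    expect_equal(perpendicular_force(v, "extension", 5), -f)
  }
  expect_equal(perpendicular_force(c(100, 0, 0), "flexion", 0), c(0, 0, 0))
  expect_error(perpendicular_force(c(0, 0, 1), "flexion", 1), "nonzero")
})

test_that("the safety limiter clamps magnitude and preserves direction", {
  lim <- 100
  v <- c(30, -40, 0)  # |v| = 50, under the limit
  expect_identical(safety_limiter(v, lim), v)
  v3 <- 3 * lim * c(1, 2, 2) / 3  # |v3| = 3*lim
  out <- safety_limiter(v3, lim)
  expect_equal(sqrt(sum(out^2)), lim, tolerance = 1e-12)
  expect_equal(out / sqrt(sum(out^2)), v3 / sqrt(sum(v3^2)),
               tolerance = 1e-12)
  set.seed(53)
  for (i in 1:50) {
    v <- stats::rnorm(3, 0, 150)
    out <- safety_limiter(v, lim)
    expect_equal(sqrt(sum(out^2)), min(sqrt(sum(v^2)), lim),
                 tolerance = 1e-9)
  }
})

test_that("height hold corrects toward the set height and settles under gravity", {
  expect_equal(height_hold(250, 250), 0)
  expect_gt(height_hold(240, 250), 0)  # below -> upward force
  expect_lt(height_hold(260, 250), 0)
  # closed loop: point mass under gravity with viscous damping, P-control
  m <- 0.5; gravity <- 9.81; damp <- 20; dt <- 0.001
  z <- 250; vz <- 0; set_h <- 250
  for (i in seq_len(10000)) {  # 10 s
    fz <- height_hold(z, set_h) - m * gravity - damp * vz / 1000
    vz <- vz + fz / m * dt * 1000  # mm/s
    z <- z + vz * dt
  }
  expect_lt(abs(z - set_h), 1)  # steady-state error below 1 mm
})

test_that("linear plants are measured at the analytic held force", {
  cfg <- haptic_config()  # threshold 15 deg, ramp 1 N/s, step 1 ms
  res <- run_haptic_measurement(wrist_plant(stiffness_n_per_deg = 0.5), cfg)
  expect_identical(res$outcome, "completed")
  expect_lt(abs(res$force_n - 7.5),
            cfg$ramp_rate_n_per_s * cfg$control_step_s + 1e-12)
  expect_gte(res$angle_deg, cfg$threshold_angle_deg - 1e-9)
})

test_that("a zero threshold completes immediately at zero force", {
  res <- run_haptic_measurement(wrist_plant(),
                                haptic_config(threshold_angle_deg = 0))
  expect_identical(res$outcome, "completed")
  expect_equal(res$force_n, 0)
  expect_gte(res$angle_deg, 0)
})

test_that("unreachable thresholds terminate force-capped at exactly the cap", {
  # gain 0.5 deg/N: 15 deg needs 30 N, far beyond the 12 N cap
  res <- run_haptic_measurement(wrist_plant(stiffness_n_per_deg = 2),
                                haptic_config())
  expect_identical(res$outcome, "force-capped")
  expect_identical(res$force_n, 12)
  expect_equal(res$angle_deg, 6, tolerance = 1e-6)
})

test_that("the force ramp is non-decreasing then constant after the threshold", {
  res <- run_haptic_measurement(wrist_plant(stiffness_n_per_deg = 0.5),
                                haptic_config())
  f <- res$series$force_n
  expect_true(all(diff(f) >= 0))
  crossed <- which(res$series$angle_deg >= 15)[1]
  expect_true(all(diff(f[(crossed + 1):length(f)]) == 0))
})

test_that("perpendicularity and the speed limit hold at every control step", {
  res <- run_haptic_measurement(wrist_plant(stiffness_n_per_deg = 0.5),
                                haptic_config())
  expect_lt(max(res$series$perp_dot), 1e-9)
  expect_lte(max(res$series$speed_mm_per_s),
             haptic_config()$speed_limit_mm_per_s + 1e-9)
})

test_that("a plant that never settles within budget is reported unstable", {
  # heavy damping lag + tiny epsilon: the angle keeps creeping past budget
  plant <- wrist_plant(stiffness_n_per_deg = 0.5, damping_n_s_per_deg = 50)
  cfg <- haptic_config(stability_epsilon_deg = 1e-7, max_session_s = 3)
  res <- run_haptic_measurement(plant, cfg)
  expect_identical(res$outcome, "unstable")
})

test_that("extension sessions mirror flexion and honour asymmetry", {
  plant <- wrist_plant(stiffness_n_per_deg = 0.5, extension_factor = 2)
  flex <- run_haptic_measurement(plant, haptic_config(direction = "flexion"))
  ext <- run_haptic_measurement(plant, haptic_config(direction = "extension"))
  expect_identical(ext$direction, "extension")
  # gain 4 deg/N in extension: held force 15/4
  expect_lt(abs(ext$force_n - 3.75), 0.001 + 1e-12)
  expect_lt(abs(flex$force_n - 7.5), 0.001 + 1e-12)
  # effector swings to opposite sides of the entry vector
  expect_gt(flex$current[2], 0)
  expect_lt(ext$current[2], 0)
})
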