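test_that("a 4.2 m walk of 0.6 m steps yields 7 footsteps spaced exactly 0.6 m", {
  p <- gait_params(step_length = 0.6, step_width = 0.1, cadence = 2.0,
                   walk_distance = 4.2, noise_sd = 0)
  s <- simulate_walk(p)
  fs <- s$truth$footsteps
  expect_identical(nrow(fs), 7L)
  expect_equal(diff(fs$x), rep(0.6, 6), tolerance = 1e-12)
  expect_identical(fs$side, rep(c("L", "R"), length.out = 7))
  expect_true(all(diff(fs$midstance_time) > 0))
})

test_that("heel AP velocity is identically zero during every stance (noiseless)", {
  p <- default_params()
  s <- simulate_walk(p)
  t <- traj_time(s$traj)
  Ts <- 1 / p$cadence
  sw_dur <- (1 - p$stance_fraction) * 2 * Ts
  for (side in c("L", "R")) {
    x <- keypoint_xyz(s$traj, paste0(ifelse(side == "L", "left", "right"), "_heel"))[, "x"]
    idx <- if (side == "L") seq(1, p$n_steps, 2) else seq(2, p$n_steps, 2)
    lands <- s$truth$bout_start + (idx - 1) * Ts + sw_dur
    nxt <- s$truth$bout_start + (idx + 1) * Ts
    for (i in seq_along(lands)) {
      win <- t > lands[i] + 1e-9 & t < min(nxt[i], max(t)) - 1e-9
      expect_lt(diff(range(x[win])), 1e-12)
    }
  }
})

test_that("the same seed reproduces bit-identical noisy trajectories", {
  p <- default_params(noise_sd = 0.004, seed = 99)
  a <- simulate_walk(p)
  b <- simulate_walk(p)
  expect_identical(a$traj$positions, b$traj$positions)
  expect_identical(a$truth$footsteps, b$truth$footsteps)
  c <- simulate_walk(default_params(noise_sd = 0.004, seed = 100))
  expect_false(identical(a$traj$positions, c$traj$positions))
})

test_that("simulation does not disturb the caller's RNG stream", {
  set.seed(123)
  first <- stats::rnorm(1)
  set.seed(123)
  invisible(simulate_walk(default_params(noise_sd = 0.002)))
  expect_identical(stats::rnorm(1), first)
})

test_that("ground-truth step lengths telescope to the AP footstep span", {
  for (L in c(0.4, 0.65)) {
    s <- simulate_walk(default_params(step_length = L))
    fs <- s$truth$footsteps
    expect_equal(sum(diff(fs$x)), fs$x[nrow(fs)] - fs$x[1], tolerance = 1e-12)
  }
})

test_that("inconsistent parameters are rejected with informative messages", {
  expect_error(gait_params(step_length = 0.6, walk_distance = 1.5), "at least 4")
  expect_error(gait_params(stance_fraction = 0.4), "stance_fraction")
  expect_error(gait_params(step_length = -1), "must be > 0")
  expect_error(gait_params(noise_sd = -0.001), "noise_sd")
})

test_that("pivot trials carry a turn interval of exactly the requested length", {
  p <- default_params()
  for (D in c(2.5, 4.0)) {
    s <- simulate_pivot_trial(p, D)
    expect_equal(diff(s$truth$turn_interval), D,
                 tolerance = 1 / p$sample_rate)
  }
  expect_error(simulate_pivot_trial(p, -1), "turn_duration")
  expect_error(simulate_pivot_trial(p, 30), "longer than the trial")
})

test_that("the pivot head AP position has a unique global maximum inside the turn", {
  s <- simulate_pivot_trial(default_params(), 2.5)
  x <- rowMeans(sapply(c("left_ear", "right_ear", "nose"),
                       function(k) keypoint_xyz(s$traj, k)[, "x"]))
  tt <- traj_time(s$traj)
  i <- which.max(x)
  expect_identical(sum(x == max(x)), 1L)
  expect_gt(tt[i], s$truth$turn_interval[1])
  expect_lt(tt[i], s$truth$turn_interval[2])
})

test_that("two-system streams sample the same motion (sampling closure)", {
  p <- gait_params(step_length = 0.6, cadence = 2.0, walk_distance = 4,
                   noise_sd = 0)
  ts <- simulate_two_systems(p, lag = 0, markered_rate = 240,
                             markerless_noise_sd = 0)
  idx <- seq(1, by = 240 / 30, length.out = n_samples(ts$markerless))
  for (pair in list(c("left_foot", "left_heel"), c("right_foot", "right_heel"))) {
    a <- ts$markered$positions[idx, pair[1], ]
    b <- ts$markerless$positions[, pair[2], ]
    expect_lt(max(abs(a - b)), 1e-6)
  }
  expect_identical(ts$truth$imposed_lag, 0)
})

test_that("two-system ground truth records the imposed lag and sample budget", {
  p <- gait_params(step_length = 0.6, cadence = 2.0, walk_distance = 4)
  ts <- simulate_two_systems(p, lag = 0.25)
  expect_identical(ts$truth$imposed_lag, 0.25)
  # duration follows from the speed profile: trial length = last sample time
  dur <- max(ts$truth$speed_profile$t)
  expect_lte(abs(n_samples(ts$markered) - 240 * dur), 1.5)
  expect_error(simulate_two_systems(p, lag = 3), "lag")
  expect_error(simulate_two_systems(p, markered_rate = 10), "markered_rate")
})

test_that("an obstacle step raises exactly one swing apex in the ground truth", {
  p <- default_params(obstacle_step = 5, obstacle_apex = 0.2)
  s <- simulate_walk(p)
  expect_equal(s$truth$obstacle_crossing$step, 5)
  expect_equal(s$truth$obstacle_crossing$clearance, 0.15, tolerance = 1e-12)
  z <- keypoint_xyz(s$traj, "left_heel")[, "z"]
  expect_equal(max(z), 0.2, tolerance = 1e-6)  # step 5 is a left swing
})
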