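test_that("time alignment of identical signals gives zero lag and unit peak", {
  s <- simulate_walk(default_params())
  ss <- sum_foot_speed(s$traj)
  al <- time_align(ss, ss)
  expect_equal(al$lag, 0)
  expect_equal(al$peak_corr, 1, tolerance = 1e-9)
})

test_that("an imposed 0.25 s inter-system lag is recovered to one sample", {
  p <- gait_params(step_length = 0.6, cadence = 2.0, walk_distance = 4)
  ts <- simulate_two_systems(p, lag = 0.25)
  al <- time_align(sum_foot_speed(ts$markerless), sum_foot_speed(ts$markered))
  expect_lte(abs(al$lag - 0.25), 1 / 240 + 1e-9)
  expect_gt(al$peak_corr, 0.99)
  expect_equal(al$resampled_rate, 240)
})

test_that("time alignment equals a brute-force all-shifts argmax on toys", {
  set.seed(21)
  for (rep in 1:5) {
    base <- as.numeric(stats::filter(stats::rnorm(400), rep(1 / 6, 6), sides = 2))
    base[is.na(base)] <- 0
    shift <- sample(-20:20, 1)
    a <- abs(base[101:300]) + 0.3                  # 200-sample toys, same rate
    b <- abs(base[(101 + shift):(300 + shift)]) + 0.3
    sa <- scalar_series(a, 30); sb <- scalar_series(b, 30)
    al <- time_align(sa, sb, max_lag = 1.5, min_peak_corr = 0.2)
    oracle <- brute_force_lag(sa$values, sb$values, 45)
    expect_equal(al$lag, -oracle / 30, tolerance = 1e-9)
  }
})

test_that("low-confidence alignment is refused", {
  a <- scalar_series(abs(stats::rnorm(300, 0, 0.01)), 30)
  b <- scalar_series(abs(stats::rnorm(300, 0, 0.01)), 30)
  err <- tryCatch(time_align(a, b), error = identity)
  expect_s3_class(err, "gaitfga_low_confidence")
})

test_that("spatial registration removes a constant offset exactly", {
  s <- simulate_walk(default_params())
  b <- s$traj
  for (k in keypoint_names(b)) b$positions[, k, ] <-
    sweep(keypoint_xyz(b, k), 2, c(0.3, -0.1, 0), `+`)
  reg <- spatial_register(s$traj, b)
  expect_lt(max(abs(reg$positions - s$traj$positions)), 1e-9)
  # already-coincident pair is unchanged
  reg2 <- spatial_register(s$traj, s$traj)
  expect_identical(reg2$positions, s$traj$positions)
})

test_that("OLS with CIs reproduces perfect fits and the textbook triple", {
  x <- 1:10
  fit <- suppressWarnings(ols_with_ci(x, x))
  expect_equal(fit$slope, 1, tolerance = 1e-12)
  expect_equal(fit$intercept, 0, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_lt(diff(fit$slope_ci), 1e-9)

  fit2 <- suppressWarnings(ols_with_ci(x, 2 * x + 1))
  expect_equal(fit2$slope, 2, tolerance = 1e-12)
  expect_equal(fit2$intercept, 1, tolerance = 1e-12)

  # closed-form OLS by hand: x = (1,2,3), y = (1,2,4)
  fit3 <- ols_with_ci(c(1, 2, 3), c(1, 2, 4))
  expect_equal(fit3$slope, 1.5, tolerance = 1e-12)
  expect_equal(fit3$intercept, -2 / 3, tolerance = 1e-12)

  expect_error(ols_with_ci(rep(1, 5), 1:5), "constant")
  expect_error(ols_with_ci(1:2, 1:2), "at least 3")
})

test_that("Bland-Altman reproduces hand-computed limits", {
  a <- c(1, 2, 3)
  expect_equal(unlist(bland_altman(a, a)[c("mean_diff", "loa_low", "loa_high")]),
               c(mean_diff = 0, loa_low = 0, loa_high = 0))

  ba <- bland_altman(a, a - 0.003)
  expect_equal(ba$mean_diff, 0.003, tolerance = 1e-12)
  expect_equal(ba$loa_high - ba$loa_low, 0, tolerance = 1e-12)

  # d = {-0.01, +0.01}: mean 0, sd = 0.01414..., LoA = +/- 0.02772
  ba2 <- bland_altman(c(0.99, 1.01), c(1, 1))
  expect_equal(ba2$mean_diff, 0, tolerance = 1e-12)
  expect_equal(ba2$sd_diff, sqrt(2) * 0.01, tolerance = 1e-9)
  expect_equal(ba2$loa_high, 1.96 * sqrt(2) * 0.01, tolerance = 1e-9)
  expect_error(bland_altman(1:3, 1:4), "equal length")
})

test_that("Bland-Altman mean difference is antisymmetric in its arguments", {
  set.seed(5)
  a <- stats::rnorm(30); b <- a + stats::rnorm(30, 0.01, 0.02)
  f <- bland_altman(a, b); g <- bland_altman(b, a)
  expect_equal(f$mean_diff, -g$mean_diff, tolerance = 1e-12)
  expect_equal(f$loa_high, -g$loa_low, tolerance = 1e-12)
})

test_that("step pairing matches identical lists and reports orphans", {
  s <- simulate_walk(default_params())
  ev <- find_footsteps(s$traj)
  st <- steps_with_times(step_metrics(ev$footsteps), ev$footsteps)
  pr <- pair_steps(st, st)
  expect_identical(nrow(pr$pairs), nrow(st))
  expect_length(pr$unmatched_a, 0)
  expect_equal(pr$pairs$step_length_a, pr$pairs$step_length_b)

  short <- st[-nrow(st), ]
  pr2 <- pair_steps(st, short)
  expect_identical(nrow(pr2$pairs), nrow(short))
  expect_identical(pr2$unmatched_a, nrow(st))

  jit <- st
  set.seed(2)
  jit$t <- jit$t + stats::runif(nrow(jit), -0.05, 0.05)
  pr3 <- pair_steps(st, jit)
  expect_identical(nrow(pr3$pairs), nrow(st))
})

test_that("full two-system validation recovers the agreement regime", {
  set.seed(42)
  sl_ml <- c(); sl_mk <- c()
  for (i in 1:12) {
    L <- stats::runif(1, 0.45, 0.7)
    W <- if (i %% 2) 0.1 else 0.25   # normal and wide width conditions
    p <- gait_params(step_length = L, step_width = W, cadence = 2.0,
                     walk_distance = 4, seed = i)
    ts <- simulate_two_systems(p, lag = 0.2, markerless_noise_sd = 0.003)
    r <- suppressWarnings(compare_systems(ts$markerless, ts$markered))
    expect_lte(abs(r$alignment$lag - 0.2), 2 / 240)
    sl_ml <- c(sl_ml, r$pairs$step_length_a)
    sl_mk <- c(sl_mk, r$pairs$step_length_b)
  }
  fit <- ols_with_ci(sl_ml, sl_mk)
  expect_gt(fit$slope, 0.97); expect_lt(fit$slope, 1.03)
  expect_lt(abs(fit$intercept), 0.01)
  expect_gt(fit$r_squared, 0.95)
})
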