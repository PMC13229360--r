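test_that("foot speed tracks stationary and uniformly translating feet", {
  n <- 150; fs <- 30
  kp <- c("left_heel", "right_heel", "left_ear", "right_ear", "nose")
  pos <- array(0, dim = c(n, 5, 3), dimnames = list(NULL, kp, NULL))
  t <- (seq_len(n) - 1) / fs
  pos[, "right_heel", 1] <- 1.0 * t
  traj <- kpt_traj(pos, fs, 0, "walkway")
  vL <- foot_speed(traj, "L")
  vR <- foot_speed(traj, "R")
  expect_lt(max(vL$values), 1e-9)
  expect_lt(max(abs(vR$values[20:130] - 1.0)), 1e-6)
  expect_true(all(vR$values >= 0))
})

test_that("noiseless simulator stance speed is small away from the crossings", {
  p <- default_params()
  s <- simulate_walk(p)
  sp <- foot_speed(s$traj, "L")
  tt <- series_time(sp)
  Ts <- 1 / p$cadence; sw <- (1 - p$stance_fraction) * 2 * Ts
  # interior of each left stance, excluding the smoother's support (~0.1 s)
  for (i in seq(1, p$n_steps - 2, 2)) {
    land <- s$truth$bout_start + (i - 1) * Ts + sw
    nxt <- s$truth$bout_start + (i + 1) * Ts
    win <- tt > land + 0.1 & tt < nxt - 0.1
    expect_lte(max(sp$values[win]), 0.05)
  }
})

test_that("stances of a noiseless walk match ground truth to one sample", {
  p <- default_params()
  s <- simulate_walk(p)
  ev <- find_footsteps(s$traj)
  truth <- s$truth$footsteps
  expect_identical(nrow(ev$footsteps), nrow(truth))
  expect_identical(ev$footsteps$side, truth$side)
  expect_lte(max(abs(ev$footsteps$midstance_time - truth$midstance_time)),
             1 / p$sample_rate + 1e-9)
  expect_lte(max(abs(ev$footsteps$x - truth$x)), 1e-6)
  expect_lte(max(abs(ev$footsteps$y - truth$y)), 1e-6)
  expect_identical(ev$flags, character(0))
})

test_that("degenerate speed series produce the degenerate stance answers", {
  n <- 90; fs <- 30
  kp <- c("left_heel", "right_heel", "left_ear", "right_ear", "nose")
  pos <- array(0, dim = c(n, 5, 3), dimnames = list(NULL, kp, NULL))
  traj <- kpt_traj(pos, fs, 0, "walkway")
  zero <- scalar_series(rep(0, n), fs, 0, "m/s")
  st <- detect_stances(zero, traj, "L")
  expect_identical(nrow(st), 1L)
  expect_equal(st$start, 0)
  expect_equal(st$end, (n - 1) / fs)

  fast <- scalar_series(rep(1, n), fs, 0, "m/s")
  expect_identical(nrow(detect_stances(fast, traj, "L")), 0L)
})

test_that("footstep count matches ground truth over the cadence/length grid", {
  for (cad in c(1.5, 2.5)) for (L in c(0.3, 0.8)) {
    s <- simulate_walk(default_params(step_length = L, cadence = cad))
    ev <- find_footsteps(s$traj)
    expect_identical(nrow(ev$footsteps), nrow(s$truth$footsteps))
  }
})

test_that("templates obey their construction contracts", {
  tp <- make_templates(2.0, 1.2, 30)
  expect_identical(length(tp$init$values), 45L)          # 2/2 + 0.5 s at 30 Hz
  expect_equal(tp$term$values, rev(tp$init$values))
  # full swing pulse peak: pi * v / (2 (1 - stance_fraction))
  expect_equal(max(tp$init$values), pi * 1.2 / (2 * 0.4), tolerance = 1e-9)
})

test_that("bout boundaries of a noiseless walk are recovered to two samples", {
  p <- default_params()
  s <- simulate_walk(p)
  cfg <- event_config(template_cadence = p$cadence, template_speed = p$steady_speed)
  bout <- detect_bout(sum_foot_speed(s$traj, cfg), cfg)
  expect_lte(abs(bout$t_start - s$truth$bout_start), 2 / p$sample_rate + 1e-9)
  expect_lte(abs(bout$t_end - s$truth$bout_end), 2 / p$sample_rate + 1e-9)
  expect_gt(bout$corr_start, 0.9)
  expect_lt(bout$t_start, bout$t_end)
})

test_that("pure quiet standing raises a low-confidence error naming the template", {
  quiet <- scalar_series(abs(stats::rnorm(300, 0, 0.005)), 30, 0, "m/s")
  cfg <- event_config(template_cadence = 2, template_speed = 1.2)
  err <- tryCatch(detect_bout(quiet, cfg), error = identity)
  expect_s3_class(err, "gaitfga_low_confidence")
  expect_match(conditionMessage(err), "gait-initiation")
})

test_that("detect_bout is shift-equivariant under integer sample shifts", {
  p <- default_params()
  s <- simulate_walk(p)
  cfg <- event_config(template_cadence = p$cadence, template_speed = p$steady_speed)
  ss <- sum_foot_speed(s$traj, cfg)
  base <- detect_bout(ss, cfg)
  for (k in c(7L, 23L)) {
    shifted <- scalar_series(c(rep(0, k), ss$values), ss$sample_rate, ss$t0, ss$units)
    b2 <- detect_bout(shifted, cfg)
    expect_equal(b2$t_start - base$t_start, k / ss$sample_rate, tolerance = 1e-9)
    expect_equal(b2$t_end - base$t_end, k / ss$sample_rate, tolerance = 1e-9)
  }
})

test_that("normalized cross-correlation matches the brute-force cor() oracle", {
  set.seed(11)
  for (rep in 1:5) {
    x <- stats::rnorm(200)
    tpl <- x[60:100] + stats::rnorm(41, 0, 0.1)
    got <- norm_xcorr(x, tpl)
    oracle <- vapply(got$lag, function(k)
      suppressWarnings(stats::cor(x[(k + 1):(k + length(tpl))], tpl)), numeric(1))
    expect_equal(got$r, oracle, tolerance = 1e-9)
    expect_identical(got$lag[which.max(got$r)], 59L)
  }
})

test_that("broken left/right alternation is flagged, not fatal", {
  p <- default_params()
  s <- simulate_walk(p)
  tr <- s$traj
  tr$positions[, "right_heel", ] <- 0   # right foot never moves: all steps L
  cfg <- event_config(template_cadence = p$cadence, template_speed = p$steady_speed)
  ev <- find_footsteps(tr, cfg)
  expect_true(any(grepl("alternate", ev$flags)))
})

test_that("noisy footstep localization stays within max(1 cm, 3 sd)", {
  errs <- c()
  for (seed in 1:8) {
    s <- simulate_walk(default_params(noise_sd = 0.003, seed = seed))
    ev <- find_footsteps(s$traj)
    errs <- c(errs, footstep_errors(ev$footsteps, s$truth$footsteps))
  }
  expect_lte(stats::quantile(errs, 0.95), max(0.01, 3 * 0.003))
})
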