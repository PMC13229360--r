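test_that("Condition 2 reproduces every printed threshold branch", {
  cases <- list(list(1.30, 3L), list(1.15, 2L), list(1.07, 1L), list(1.02, 0L),
                list(1.25, 2L),  # upper bound belongs to the score-2 bin
                list(1.2501, 3L), list(1.00, 0L))
  for (cs in cases)
    expect_identical(score_condition2(cs[[1]], 1.0)$score, cs[[2]],
                     label = sprintf("ratio %.4f", cs[[1]]))
})

test_that("Condition 2 score is non-decreasing in the speed ratio", {
  grid <- seq(0.5, 1.6, by = 0.005)
  scores <- vapply(grid, function(r) score_condition2(r, 1)$score, integer(1))
  expect_true(all(diff(scores) >= 0))
})

test_that("Conditions 3/4 combine speed bands with the lateral cap", {
  expect_identical(score_condition34(1.00, 1.0, 0)$score, 3L)
  expect_identical(score_condition34(0.80, 1.0, 0)$score, 1L)
  expect_identical(score_condition34(0.80, 1.0, 0.3)$score, 1L)
  expect_identical(score_condition34(1.08, 1.0, 0)$score, 2L)
  expect_identical(score_condition34(0.70, 1.0, 0)$score, 0L)
  # lateral deviation beyond the limit caps an otherwise perfect trial at 1
  r <- score_condition34(1.00, 1.0, 0.20)
  expect_identical(r$score, 1L)
  expect_match(r$rule_fired, "caps")
})

test_that("Condition 5 scores the printed turn-time branches", {
  expect_identical(score_condition5(2.5, TRUE)$score, 3L)
  expect_identical(score_condition5(4.0, TRUE)$score, 2L)
  expect_identical(score_condition5(5.0, TRUE)$score, 1L)
  expect_identical(score_condition5(NA, FALSE)$score, 0L)
  expect_error(score_condition5(-1, TRUE), ">= 0")
})

test_that("Condition 6 scores clearance and crossing speed", {
  expect_identical(score_condition6(0.15, 1.0, 1.0, TRUE)$score, 3L)
  expect_identical(score_condition6(0.03, 1.0, 1.0, TRUE)$score, 2L)
  expect_identical(score_condition6(0.03, 0.70, 1.0, TRUE)$score, 1L)
  expect_identical(score_condition6(0.15, 0.70, 1.0, TRUE)$score, 1L)
  expect_identical(score_condition6(NA, NA, 1.0, FALSE)$score, 0L)
  expect_error(score_condition6(0.1, 1, 0, TRUE), "baseline")
})

test_that("every scorer refuses a non-positive baseline", {
  expect_error(score_condition2(1.2, 0), "baseline")
  expect_error(score_condition34(1.0, -1, 0), "baseline")
})

test_that("pivot-turn durations are measured from head kinematics", {
  p <- default_params()
  for (D in c(2.5, 4.0)) {
    s <- simulate_pivot_trial(p, D)
    td <- detect_turn_duration(s$traj)
    expect_true(td$completed)
    expect_lt(abs(td$duration - D), 0.2)
    expect_gt(td$t_apex, s$truth$turn_interval[1])
    expect_lt(td$t_apex, s$truth$turn_interval[2])
  }
  straight <- simulate_walk(p)
  expect_false(detect_turn_duration(straight$traj)$completed)
})

test_that("an engineered synthetic session scores (., 3, 3, 3, 3, 3, ...)", {
  d <- withr::local_tempdir()
  p <- default_params(noise_sd = 0.002, seed = 7)
  cmd_simulate("fga", d, seed = 11, params = p)
  report <- suppressWarnings(cmd_score(d))
  med <- vapply(report$conditions, function(cc) cc$median_score, numeric(1))
  expect_true(is.na(med[["1"]]))
  expect_equal(unname(med[c("2", "3", "4", "5", "6")]), rep(3, 5))
  expect_true(all(is.na(med[c("7", "8", "9", "10")])))
  expect_gt(report$baseline_speed, 0)
})

test_that("reports embed thresholds and survive a JSON round-trip", {
  d <- withr::local_tempdir()
  cmd_simulate("fga", d, seed = 5, params = default_params(noise_sd = 0.002))
  report <- suppressWarnings(cmd_score(d))
  f <- file.path(d, "fga_report.json")
  back <- read_fga_report(f)
  expect_equal(back$baseline_speed, report$baseline_speed, tolerance = 1e-12)
  expect_equal(back$thresholds$lateral_limit, 0.1524)
  expect_equal(back$conditions[["5"]]$median_score,
               report$conditions[["5"]]$median_score)
  scores <- vapply(back$conditions, function(cc)
    if (is.null(cc$median_score)) NA_real_ else as.numeric(cc$median_score), numeric(1))
  expect_equal(unname(scores[c("2", "5")]), c(3, 3))
})

test_that("a session without the baseline condition is refused", {
  s <- simulate_walk(default_params())
  expect_error(build_fga_report(list("2" = s$traj)), "Condition-1")
})

test_that("a failed trial yields a flagged unscored result, not a crash", {
  s <- simulate_walk(default_params())
  # condition-3 trial of pure standing: no gait to analyze
  n <- 200
  kp <- c("left_heel", "right_heel", "left_ear", "right_ear", "nose")
  quiet <- kpt_traj(array(0.1, dim = c(n, 5, 3), dimnames = list(NULL, kp, NULL)),
                    30, 0, "walkway")
  rep <- suppressWarnings(build_fga_report(list("1" = s$traj, "3" = quiet)))
  expect_true(is.na(rep$conditions[["3"]]$median_score))
  expect_match(rep$conditions[["3"]]$repetitions[[1]]$rule_fired, "failed")
})

test_that("three repetitions are scored individually and aggregated by median", {
  base <- simulate_walk(default_params(seed = 1))
  reps <- lapply(1:3, function(i)
    simulate_walk(default_params(noise_sd = 0.002, seed = i))$traj)
  rep <- suppressWarnings(build_fga_report(list("1" = base$traj, "2" = reps)))
  expect_length(rep$conditions[["2"]]$scores, 3)
  expect_equal(rep$conditions[["2"]]$median_score,
               stats::median(rep$conditions[["2"]]$scores))
})
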