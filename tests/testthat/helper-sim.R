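# shared fixtures built in code

default_params <- function(...) {
  args <- list(step_length = 0.65, step_width = 0.12, cadence = 2.0,
               walk_distance = 6.0, noise_sd = 0, seed = 1L)
  over <- list(...)
  args[names(over)] <- over
  do.call(gait_params, args)
}

sum_foot_speed <- function(traj, cfg = event_config()) {
  a <- foot_speed(traj, "L", cfg)
  b <- foot_speed(traj, "R", cfg)
  scalar_series(a$values + b$values, a$sample_rate, a$t0, "m/s")
}

# brute-force normalized cross-correlation oracle: plain cor() per shift
brute_force_lag <- function(a, b, max_shift) {
  shifts <- -max_shift:max_shift
  r <- vapply(shifts, function(k) {
    ia <- max(1, 1 - k):min(length(a), length(b) - k)
    if (length(ia) < 8) return(-Inf)
    suppressWarnings(stats::cor(a[ia], b[ia + k]))
  }, numeric(1))
  r[!is.finite(r)] <- -Inf
  shifts[which.max(r)]
}

# nearest-ground-truth footstep matching -> horizontal localization errors (m)
footstep_errors <- function(detected, truth) {
  vapply(seq_len(nrow(detected)), function(j) {
    k <- which.min(abs(truth$midstance_time - detected$midstance_time[j]))
    sqrt((detected$x[j] - truth$x[k])^2 + (detected$y[j] - truth$y[k])^2)
  }, numeric(1))
}
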