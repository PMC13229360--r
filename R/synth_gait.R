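#' Gait simulation parameters
#'
#' Bundles the kinematic parameters of the synthetic straight-line walking
#' generator. The steady walking speed is always derived as
#' `step_length * cadence` and is not a free parameter.
#'
#' Default values mirror the study conditions the package is designed for: a
#' 6 m marked walkway, markerless capture at 30 Hz, and quiet-standing pads
#' of 1.5 s at both ends of each trial so that bout detection has a
#' non-trivial job.
#'
#' @param step_length AP distance between consecutive footsteps (m).
#' @param step_width ML distance between left and right footstep lines (m).
#' @param cadence steps per second.
#' @param walk_distance length of the walk (m); must cover at least 4 steps.
#' @param stance_fraction fraction of the stride spent in stance, per foot;
#'   must lie in (0.5, 1) so that swings of the two feet do not overlap
#'   (the complement of double support).
#' @param swing_apex_height peak heel height during swing (m).
#' @param start_pose_lateral_offset ML offset of the walking centerline (m).
#' @param noise_sd isotropic Gaussian keypoint noise per axis per sample (m).
#' @param sample_rate markerless sampling rate (Hz).
#' @param pad quiet-standing duration before and after the walk (s).
#' @param head_height constant head keypoint height (m).
#' @param obstacle_step index of a step whose swing crosses an obstacle, or
#'   `NULL`; that swing's apex is raised to `obstacle_apex`.
#' @param obstacle_apex heel apex height of the obstacle step (m).
#' @param seed integer RNG seed for the keypoint noise.
#' @return Object of class `gait_params`; `steady_speed` is filled in.
#' @export
gait_params <- function(step_length = 0.65, step_width = 0.12, cadence = 2.0,
                        walk_distance = 6.0, stance_fraction = 0.6,
                        swing_apex_height = 0.05, start_pose_lateral_offset = 0,
                        noise_sd = 0, sample_rate = 30, pad = 1.5,
                        head_height = 1.55, obstacle_step = NULL,
                        obstacle_apex = 0.20, seed = 1L) {
  if (step_length <= 0 || cadence <= 0 || sample_rate <= 0 || step_width < 0)
    stop("step_length, cadence and sample_rate must be > 0; step_width >= 0")
  if (stance_fraction <= 0.5 || stance_fraction >= 1)
    stop("stance_fraction must lie in (0.5, 1): swings of the two feet must not overlap")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (pad < 1) stop("quiet-standing pad must be >= 1 s")
  n_steps <- floor(walk_distance / step_length + 1e-9)
  if (n_steps < 4)
    stop(sprintf("walk_distance = %g m covers only %d step(s) of %g m; at least 4 are required",
                 walk_distance, n_steps, step_length))
  if (!is.null(obstacle_step) &&
      (obstacle_step < 2 || obstacle_step > n_steps - 1))
    stop("obstacle_step must be an interior step index (2 .. n_steps-1)")
  structure(list(
    step_length = step_length, step_width = step_width, cadence = cadence,
    steady_speed = step_length * cadence, walk_distance = walk_distance,
    n_steps = n_steps, stance_fraction = stance_fraction,
    swing_apex_height = swing_apex_height,
    start_pose_lateral_offset = start_pose_lateral_offset,
    noise_sd = noise_sd, sample_rate = sample_rate, pad = pad,
    head_height = head_height, obstacle_step = obstacle_step,
    obstacle_apex = obstacle_apex, seed = as.integer(seed)),
    class = "gait_params")
}

# run expr with a locally seeded RNG, restoring the caller's RNG state
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# ---- closed-form building blocks --------------------------------------------

# AP position of one foot given its swing list (data.frame onset, dur, from, adv).
# Raised-cosine displacement: stationary in stance, C1 bell-shaped swing speed.
foot_track_x <- function(t, x0, swings) {
  x <- rep(x0, length(t))
  if (!nrow(swings)) return(x)
  for (i in seq_len(nrow(swings))) {
    sw <- swings[i, ]
    u <- (t - sw$onset) / sw$dur
    inside <- u > 0 & u < 1
    x[inside] <- sw$from + sw$adv * (1 - cos(pi * u[inside])) / 2
    x[u >= 1] <- sw$from + sw$adv
  }
  x
}

# heel height: half-sine bump of the given apex during each swing
foot_track_z <- function(t, swings) {
  z <- numeric(length(t))
  if (!nrow(swings)) return(z)
  for (i in seq_len(nrow(swings))) {
    sw <- swings[i, ]
    u <- (t - sw$onset) / sw$dur
    inside <- u > 0 & u < 1
    z[inside] <- sw$apex * sin(pi * u[inside])
  }
  z
}

# piecewise speed profile: data.frame(t_start, dur, type, v0, v1) with types
# "const", "cosramp" (raised-cosine v0 -> v1) and "linear". Returns closed-form
# position (exact integral, zero before the first segment and frozen after the
# last) and speed at the requested times.
speed_profile_eval <- function(t, segs, x0 = 0) {
  seg_dist <- function(s) switch(s$type,
    const   = s$v0 * s$dur,
    cosramp = (s$v0 + s$v1) / 2 * s$dur,
    linear  = (s$v0 + s$v1) / 2 * s$dur)
  x <- rep(x0, length(t))
  v <- numeric(length(t))
  base <- x0
  for (i in seq_len(nrow(segs))) {
    s <- segs[i, ]
    tau <- t - s$t_start
    inside <- tau > 0 & tau <= s$dur
    after <- tau > s$dur
    if (any(inside)) {
      ti <- tau[inside]
      if (s$type == "const") {
        x[inside] <- base + s$v0 * ti
        v[inside] <- s$v0
      } else if (s$type == "cosramp") {
        # v(tau) = v0 + (v1-v0) * (1 - cos(pi tau/dur)) / 2
        x[inside] <- base + s$v0 * ti +
          (s$v1 - s$v0) / 2 * (ti - s$dur / pi * sin(pi * ti / s$dur))
        v[inside] <- s$v0 + (s$v1 - s$v0) * (1 - cos(pi * ti / s$dur)) / 2
      } else {
        x[inside] <- base + s$v0 * ti + (s$v1 - s$v0) * ti^2 / (2 * s$dur)
        v[inside] <- s$v0 + (s$v1 - s$v0) * ti / s$dur
      }
    }
    base <- base + seg_dist(s)
    x[after] <- base
    v[after] <- 0  # overwritten by later segments if any
  }
  # speed after the final segment is the final segment's end value only if
  # nonzero-duration continuation exists; profiles here always end at 0.
  list(x = x, v = v)
}

seg_row <- function(t_start, dur, type, v0, v1 = v0)
  data.frame(t_start = t_start, dur = dur, type = type, v0 = v0, v1 = v1)

# build the swing schedule of a straight walk: step i lands at i * step_length;
# the first swing advances one step length, later swings advance two.
walk_swings <- function(p) {
  Ts <- 1 / p$cadence
  sw_dur <- (1 - p$stance_fraction) * 2 * Ts
  n <- p$n_steps
  onset <- p$pad + (seq_len(n) - 1) * Ts
  side <- rep(c("L", "R"), length.out = n)
  from <- ifelse(seq_len(n) <= 2, 0, (seq_len(n) - 2) * p$step_length)
  adv <- ifelse(seq_len(n) == 1, p$step_length, 2 * p$step_length)
  apex <- rep(p$swing_apex_height, n)
  if (!is.null(p$obstacle_step)) apex[p$obstacle_step] <- p$obstacle_apex
  data.frame(i = seq_len(n), onset = onset, dur = sw_dur, side = side,
             from = from, adv = adv, apex = apex,
             land = onset + sw_dur, x_land = seq_len(n) * p$step_length)
}

# ground-truth midstance per footstep: midpoint of the foot's stationary
# interval (landing to the same foot's next lift-off, or to trial end).
truth_footsteps <- function(swings, p, t_end) {
  n <- nrow(swings)
  next_onset <- vapply(seq_len(n), function(i) {
    later <- swings$onset[swings$side == swings$side[i] & swings$i > i]
    if (length(later)) min(later) else t_end
  }, numeric(1))
  y <- ifelse(swings$side == "L", p$step_width / 2, -p$step_width / 2) +
    p$start_pose_lateral_offset
  data.frame(side = swings$side,
             midstance_time = (swings$land + next_onset) / 2,
             x = swings$x_land, y = y, z = 0)
}

# assemble a markerless keypoint array from closed-form tracks
assemble_markerless <- function(t, xL, zL, xR, zR, head_x, p,
                                heading = NULL, head_y = NULL) {
  nT <- length(t)
  yoff <- p$start_pose_lateral_offset
  if (is.null(heading)) heading <- numeric(nT)
  if (is.null(head_y)) head_y <- rep(yoff, nT)
  ch <- cos(heading); sh <- sin(heading)
  yL <- yoff + (p$step_width / 2) * ch
  yR <- yoff - (p$step_width / 2) * ch
  kp <- c("left_heel", "right_heel", "left_ear", "right_ear", "nose")
  pos <- array(0, dim = c(nT, length(kp), 3), dimnames = list(NULL, kp, c("x", "y", "z")))
  pos[, "left_heel", ] <- cbind(xL, yL, zL)
  pos[, "right_heel", ] <- cbind(xR, yR, zR)
  # rigid head offsets, rotated with the heading: ears +-0.08 m lateral,
  # nose +0.10 m forward and 0.05 m below the ear line
  ear_dy <- 0.08; nose_dx <- 0.10
  pos[, "left_ear", ]  <- cbind(head_x - ear_dy * sh, head_y + ear_dy * ch,
                                rep(p$head_height, nT))
  pos[, "right_ear", ] <- cbind(head_x + ear_dy * sh, head_y - ear_dy * ch,
                                rep(p$head_height, nT))
  pos[, "nose", ]      <- cbind(head_x + nose_dx * ch, head_y + nose_dx * sh,
                                rep(p$head_height - 0.05, nT))
  pos
}

add_noise <- function(pos, sd, seed) {
  if (sd <= 0) return(pos)
  with_local_seed(seed, pos + array(stats::rnorm(length(pos), 0, sd), dim = dim(pos)))
}

# head progression profile of a straight walk: raised-cosine speed ramps (one
# step period each) around a steady plateau, total displacement equal to the
# mid-feet displacement (n - 1/2) * step_length.
walk_head_segments <- function(p) {
  Ts <- 1 / p$cadence
  v <- p$steady_speed
  X <- (p$n_steps - 0.5) * p$step_length
  steady <- X / v - Ts
  rbind(seg_row(p$pad, Ts, "cosramp", 0, v),
        seg_row(p$pad + Ts, steady, "const", v),
        seg_row(p$pad + Ts + steady, Ts, "cosramp", v, 0))
}

#' Simulate a straight walking bout with exact ground truth
#'
#' Generates markerless keypoint trajectories (left/right heel, left/right
#' ear, nose) of a straight walk down the walkway. Heel motion is piecewise:
#' exactly stationary in stance and raised-cosine in swing (a C1 bell-shaped
#' swing-speed pulse); step `i` lands at `i * step_length` on alternating
#' sides of the centerline. The head keypoints follow a smooth whole-body
#' progression profile (cosine-ramped trapezoidal speed) at the steady speed
#' `step_length * cadence`. Isotropic Gaussian noise is added per sample when
#' `noise_sd > 0`.
#'
#' @param params a [gait_params()] object.
#' @return A list with elements `traj` (a [kpt_traj()], walkway frame) and
#'   `truth` (class `gait_truth`: `footsteps` data frame with side,
#'   midstance_time and location; `bout_start`/`bout_end`; sampled
#'   `speed_profile`; `obstacle_crossing` when an obstacle step was simulated).
#' @export
simulate_walk <- function(params) {
  stopifnot(inherits(params, "gait_params"))
  p <- params
  sw <- walk_swings(p)
  segs <- walk_head_segments(p)
  t_end <- max(sw$land[nrow(sw)], segs$t_start[3] + segs$dur[3]) + p$pad
  nT <- floor(t_end * p$sample_rate) + 1L
  t <- (seq_len(nT) - 1) / p$sample_rate

  swL <- sw[sw$side == "L", ]; swR <- sw[sw$side == "R", ]
  xL <- foot_track_x(t, 0, swL); zL <- foot_track_z(t, swL)
  xR <- foot_track_x(t, 0, swR); zR <- foot_track_z(t, swR)
  head <- speed_profile_eval(t, segs)
  pos <- assemble_markerless(t, xL, zL, xR, zR, head$x, p)
  pos <- add_noise(pos, p$noise_sd, p$seed)
  traj <- kpt_traj(pos, p$sample_rate, 0, frame_tag = "walkway")

  truth <- structure(list(
    footsteps = truth_footsteps(sw, p, t[nT]),
    bout_start = sw$onset[1], bout_end = sw$land[nrow(sw)],
    speed_profile = list(t = t, v = head$v),
    imposed_lag = NULL, turn_interval = NULL,
    obstacle_crossing = if (!is.null(p$obstacle_step))
      list(step = p$obstacle_step,
           apex = p$obstacle_apex,
           clearance = p$obstacle_apex - p$swing_apex_height) else NULL,
    params = list(step_length = p$step_length, step_width = p$step_width,
                  cadence = p$cadence, steady_speed = p$steady_speed,
                  n_steps = p$n_steps)),
    class = "gait_truth")
  list(traj = traj, truth = truth)
}

#' Simulate a gait-and-pivot-turn trial
#'
#' The subject walks half of `walk_distance` forward, reverses heading 180
#' degrees over `turn_duration`, and walks back. The head AP speed passes
#' from `+steady_speed` to `-steady_speed` through a brief deceleration ramp
#' (`turn_ramp` s) at each end of the turn interval and a near-zero drift in
#' between, so the AP head position has a unique global maximum inside the
#' turn. Feet hold their position during the turn; footstep alternation
#' continues through the inbound walk.
#'
#' @param params a [gait_params()].
#' @param turn_duration imposed turn interval length in seconds (> 0).
#' @param turn_ramp deceleration/acceleration ramp inside the turn (s).
#' @return As [simulate_walk()]; `truth$turn_interval` holds `c(start, end)`
#'   with `end - start == turn_duration`.
#' @export
simulate_pivot_trial <- function(params, turn_duration, turn_ramp = 0.1) {
  stopifnot(inherits(params, "gait_params"))
  p <- params
  if (turn_duration <= 0) stop("turn_duration must be > 0")
  if (turn_duration > 15) stop("turn_duration longer than the trial; must be <= 15 s")
  if (turn_duration <= 2.5 * turn_ramp) stop("turn_duration too short for the turn ramps")
  Ts <- 1 / p$cadence
  sw_dur <- (1 - p$stance_fraction) * 2 * Ts
  L <- p$step_length
  n_out <- max(4, floor(p$walk_distance / 2 / L))
  v <- p$steady_speed
  beta <- turn_ramp
  drift <- 0.05  # m/s residual AP drift while turning in place

  out_sw <- walk_swings(within_params(p, n_out))
  T1 <- out_sw$land[n_out]          # turn starts when the last outbound step lands
  T2 <- T1 + turn_duration

  # inbound swings: alternation continues, each advances -2L
  in_side <- rep(c("L", "R"), length.out = n_out + 1)[-1]
  if (out_sw$side[n_out] == "R") in_side <- rev_side(in_side)
  posL <- out_sw$x_land[max(which(out_sw$side == "L"))]
  posR <- out_sw$x_land[max(which(out_sw$side == "R"))]
  in_from <- numeric(n_out); in_adv <- numeric(n_out)
  cur <- c(L = posL, R = posR)
  for (j in seq_len(n_out)) {
    s <- in_side[j]
    in_from[j] <- cur[[s]]
    in_adv[j] <- -2 * L
    cur[[s]] <- cur[[s]] - 2 * L
  }
  in_sw <- data.frame(i = n_out + seq_len(n_out), onset = T2 + (seq_len(n_out) - 1) * Ts,
                      dur = sw_dur, side = in_side, from = in_from, adv = in_adv,
                      apex = p$swing_apex_height)
  in_sw$land <- in_sw$onset + in_sw$dur
  in_sw$x_land <- in_sw$from + in_sw$adv
  all_sw <- rbind(out_sw[names(in_sw)], in_sw)

  # Head speed profile out, through the turn, and back. The turn interval is
  # defined kinematically: forward speed passes the boundary speed
  # `edge_speed` exactly at T1 and -edge_speed exactly at T2; deceleration
  # from steady speed happens just before T1, re-acceleration just after T2.
  edge <- 0.2
  segs <- rbind(
    seg_row(p$pad, Ts, "cosramp", 0, v),
    seg_row(p$pad + Ts, T1 - beta - p$pad - Ts, "const", v),
    seg_row(T1 - beta, beta, "cosramp", v, edge),
    seg_row(T1, beta, "cosramp", edge, drift),
    seg_row(T1 + beta, turn_duration - 2 * beta, "linear", drift, -drift),
    seg_row(T2 - beta, beta, "cosramp", -drift, -edge),
    seg_row(T2, beta, "cosramp", -edge, -v))
  x_acc <- speed_profile_eval(T2 + beta, segs)$x
  dur_back <- max(0, (x_acc - v * Ts / 2) / v)
  segs <- rbind(segs,
                seg_row(T2 + beta, dur_back, "const", -v),
                seg_row(T2 + beta + dur_back, Ts, "cosramp", -v, 0))
  t_end <- max(in_sw$land[n_out], T2 + beta + dur_back + Ts) + p$pad
  nT <- floor(t_end * p$sample_rate) + 1L
  t <- (seq_len(nT) - 1) / p$sample_rate

  swL <- all_sw[all_sw$side == "L", ]; swR <- all_sw[all_sw$side == "R", ]
  xL <- foot_track_x(t, 0, swL); zL <- foot_track_z(t, swL)
  xR <- foot_track_x(t, 0, swR); zR <- foot_track_z(t, swR)
  head <- speed_profile_eval(t, segs)
  heading <- pi * pmin(1, pmax(0, (t - T1) / turn_duration))
  heading <- (1 - cos(heading)) / 2 * pi  # raised-cosine 0 -> pi over the turn
  pos <- assemble_markerless(t, xL, zL, xR, zR, head$x, p, heading = heading)
  pos <- add_noise(pos, p$noise_sd, p$seed)
  traj <- kpt_traj(pos, p$sample_rate, 0, frame_tag = "walkway")

  fs_truth <- truth_footsteps(all_sw, p, t[nT])
  # heading is reversed on the inbound leg: the subject's left is at -y
  fs_truth$y[all_sw$onset >= T2] <- -fs_truth$y[all_sw$onset >= T2] +
    2 * p$start_pose_lateral_offset
  truth <- structure(list(
    footsteps = fs_truth,
    bout_start = all_sw$onset[1], bout_end = in_sw$land[n_out],
    speed_profile = list(t = t, v = head$v),
    imposed_lag = NULL, turn_interval = c(T1, T2), obstacle_crossing = NULL,
    params = list(step_length = L, step_width = p$step_width,
                  cadence = p$cadence, steady_speed = v, n_steps = 2 * n_out)),
    class = "gait_truth")
  list(traj = traj, truth = truth)
}

# shallow copy of gait_params with a different step count (internal)
within_params <- function(p, n_steps) { p$n_steps <- n_steps; p }

#' Derive modified gait parameters
#'
#' Re-validates a [gait_params()] object with some fields replaced
#' (`steady_speed` and the step count are re-derived).
#'
#' @param params a [gait_params()].
#' @param ... fields to replace (any [gait_params()] argument).
#' @return a new `gait_params` object.
#' @export
modify_params <- function(params, ...) {
  stopifnot(inherits(params, "gait_params"))
  fields <- unclass(params)
  fields$steady_speed <- NULL
  fields$n_steps <- NULL
  over <- list(...)
  unknown <- setdiff(names(over), names(fields))
  if (length(unknown)) stop("unknown gait_params field(s): ",
                            paste(unknown, collapse = ", "))
  fields[names(over)] <- over
  do.call(gait_params, fields)
}
rev_side <- function(s) ifelse(s == "L", "R", "L")

#' Simulate a paired markerless / marker-based recording
#'
#' Samples one underlying continuous walk with two virtual systems: a
#' marker-based reference (keypoints left_foot, right_foot, head) at
#' `markered_rate`, noise-free, and a markerless stream (heels, ears, nose)
#' at the `params` sampling rate, delayed by `lag` seconds and carrying its
#' own keypoint noise. Because both streams sample the same closed-form
#' motion, downsampling the reference reproduces the markerless stream
#' exactly when `lag = 0` and the noise is zero.
#'
#' @param params a [gait_params()]; `noise_sd` is ignored here in favour of
#'   `markerless_noise_sd`.
#' @param lag markerless time delay relative to the markered stream (s),
#'   `|lag| < 2`.
#' @param markered_rate reference sampling rate in Hz (>= 30).
#' @param markerless_noise_sd Gaussian keypoint noise of the markerless
#'   stream (m).
#' @return List with `markerless` and `markered` [kpt_traj()] objects and
#'   `truth` (ground truth on the markered clock, including `imposed_lag`).
#' @export
simulate_two_systems <- function(params, lag = 0, markered_rate = 240,
                                 markerless_noise_sd = 0) {
  stopifnot(inherits(params, "gait_params"))
  p <- params
  if (abs(lag) >= 2) stop("|lag| must be < 2 s")
  if (markered_rate < 30) stop("markered_rate must be >= 30 Hz")
  sw <- walk_swings(p)
  segs <- walk_head_segments(p)
  t_end <- max(sw$land[nrow(sw)], segs$t_start[3] + segs$dur[3]) + p$pad
  swL <- sw[sw$side == "L", ]; swR <- sw[sw$side == "R", ]

  eval_motion <- function(t) {
    list(xL = foot_track_x(t, 0, swL), zL = foot_track_z(t, swL),
         xR = foot_track_x(t, 0, swR), zR = foot_track_z(t, swR),
         head = speed_profile_eval(t, segs))
  }

  # markered reference: same closed forms, dedicated keypoint names
  nM <- floor(t_end * markered_rate) + 1L
  tm <- (seq_len(nM) - 1) / markered_rate
  m <- eval_motion(tm)
  kp <- c("left_foot", "right_foot", "head")
  posm <- array(0, dim = c(nM, 3, 3), dimnames = list(NULL, kp, c("x", "y", "z")))
  yoff <- p$start_pose_lateral_offset
  posm[, "left_foot", ] <- cbind(m$xL, rep(yoff + p$step_width / 2, nM), m$zL)
  posm[, "right_foot", ] <- cbind(m$xR, rep(yoff - p$step_width / 2, nM), m$zR)
  posm[, "head", ] <- cbind(m$head$x, rep(yoff, nM), rep(p$head_height, nM))
  markered <- kpt_traj(posm, markered_rate, 0, frame_tag = "walkway")

  # markerless stream: sampled on its own 30 Hz clock, motion delayed by lag
  nS <- floor(t_end * p$sample_rate) + 1L
  ts <- (seq_len(nS) - 1) / p$sample_rate
  s <- eval_motion(ts - lag)
  poss <- assemble_markerless(ts, s$xL, s$zL, s$xR, s$zR, s$head$x, p)
  poss <- add_noise(poss, markerless_noise_sd, p$seed)
  markerless <- kpt_traj(poss, p$sample_rate, 0, frame_tag = "walkway")

  truth <- structure(list(
    footsteps = truth_footsteps(sw, p, tm[nM]),
    bout_start = sw$onset[1], bout_end = sw$land[nrow(sw)],
    speed_profile = list(t = tm, v = m$head$v),
    imposed_lag = lag, turn_interval = NULL, obstacle_crossing = NULL,
    params = list(step_length = p$step_length, step_width = p$step_width,
                  cadence = p$cadence, steady_speed = p$steady_speed,
                  n_steps = p$n_steps)),
    class = "gait_truth")
  list(markerless = markerless, markered = markered, truth = truth)
}
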