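#' Step metrics from an ordered footstep sequence
#'
#' One record per pair of consecutive footsteps: step length is the AP (x)
#' displacement, signed step width the ML (y) displacement (+ toward the
#' subject's left), and the step period the midstance-time difference.
#'
#' @param footsteps time-ordered footstep data frame (`side`,
#'   `midstance_time`, `x`, `y`, `z`), e.g. from [find_footsteps()].
#' @return data frame with `index`, `leading_side`, `step_length`,
#'   `step_width_signed`, `step_width`, `step_period`; zero rows when fewer
#'   than two footsteps are supplied.
#' @export
step_metrics <- function(footsteps) {
  n <- nrow(footsteps)
  if (is.null(n) || n < 2)
    return(data.frame(index = integer(), leading_side = character(),
                      step_length = numeric(), step_width_signed = numeric(),
                      step_width = numeric(), step_period = numeric()))
  i <- 2:n
  data.frame(index = i - 1L,
             leading_side = footsteps$side[i],
             step_length = diff(footsteps$x),
             step_width_signed = diff(footsteps$y),
             step_width = abs(diff(footsteps$y)),
             step_period = diff(footsteps$midstance_time))
}

#' Head speed
#'
#' Signed AP speed of the head: the time derivative of the average forward
#' (x) position of the available head keypoints (left ear, right ear and
#' nose for the markerless dialect; the single head marker for the markered
#' dialect), smoothed at `cutoff` with the same zero-phase ringing-free
#' smoother as [foot_speed()]. Negative while walking back after a pivot
#' turn.
#'
#' @param traj a walkway-frame [kpt_traj()].
#' @param cutoff smoothing cutoff in Hz (default 3, as for foot speed).
#' @return a [scalar_series()] in m/s.
#' @export
head_speed <- function(traj, cutoff = 3) {
  kp <- keypoint_names(traj)
  heads <- intersect(c("left_ear", "right_ear", "nose"), kp)
  if (!length(heads)) heads <- intersect("head", kp)
  if (!length(heads))
    stop("no head keypoints present (need left_ear/right_ear/nose or head)")
  xs <- sapply(heads, function(k) keypoint_xyz(traj, k)[, "x"])
  x <- if (is.matrix(xs)) rowMeans(xs) else mean(xs)
  v <- derivative(scalar_series(x, traj$sample_rate, traj$t0, "m"))
  v$values <- gaussian_smooth(v$values, cutoff, v$sample_rate)
  v
}

#' Summarize a walking bout
#'
#' Aggregates the per-bout quantities used by FGA scoring: movement
#' duration, mean and maximum head speed over the bout, the maximum lateral
#' footstep deviation outside the marked walkway (relative to the centerline
#' fixed by the walkway frame), and step-width statistics.
#'
#' @param steps [step_metrics()] result for the bout.
#' @param footsteps the footstep data frame the steps were derived from.
#' @param hs [head_speed()] series of the trial.
#' @param bout bout window from [detect_bout()].
#' @param walkway_halfwidth half the marked walkway width (m; default
#'   0.1524, i.e. a 30.48 cm walkway).
#' @return list (`bout_summary`): `duration`, `mean_speed` (mean signed head
#'   speed over the bout), `mean_abs_speed`, `max_speed` (max |head speed|),
#'   `distance_speed` (AP head displacement / duration), `max_lateral_placement`,
#'   `max_step_width`, `mean_step_width`, `n_steps`, `flags`.
#' @export
bout_summary <- function(steps, footsteps, hs, bout, walkway_halfwidth = 0.1524) {
  stopifnot(inherits(hs, "scalar_series"))
  if (bout$t_end <= bout$t_start) stop("invalid bout: t_end <= t_start")
  tt <- series_time(hs)
  inb <- tt >= bout$t_start & tt <= bout$t_end
  if (!any(inb)) stop("head-speed series does not cover the bout")
  v <- hs$values[inb]
  dt <- 1 / hs$sample_rate
  flags <- character()
  if (!nrow(steps)) flags <- c(flags, "no steps in bout; width statistics undefined")
  lat <- if (nrow(footsteps)) max(pmax(0, abs(footsteps$y) - walkway_halfwidth)) else NA_real_
  list(duration = bout$t_end - bout$t_start,
       mean_speed = mean(v),
       mean_abs_speed = mean(abs(v)),
       max_speed = max(abs(v)),
       distance_speed = sum(v) * dt / (bout$t_end - bout$t_start),
       max_lateral_placement = lat,
       max_step_width = if (nrow(steps)) max(steps$step_width) else NA_real_,
       mean_step_width = if (nrow(steps)) mean(steps$step_width) else NA_real_,
       n_steps = nrow(steps),
       flags = flags)
}

#' Swing apex height per step
#'
#' For each step (footstep 2..n) the swinging foot is the leading side; its
#' apex is the maximum heel height between the two midstance instants.
#' Used to quantify obstacle clearance.
#'
#' @param traj a walkway-frame [kpt_traj()].
#' @param footsteps time-ordered footstep data frame.
#' @return numeric vector of apex heights, one per step (length
#'   `nrow(footsteps) - 1`).
#' @export
step_swing_apex <- function(traj, footsteps) {
  n <- nrow(footsteps)
  if (n < 2) return(numeric())
  tt <- traj_time(traj)
  vapply(2:n, function(i) {
    heel <- keypoint_xyz(traj, heel_name(traj, footsteps$side[i]))
    win <- tt >= footsteps$midstance_time[i - 1] & tt <= footsteps$midstance_time[i]
    if (!any(win)) return(NA_real_)
    max(heel[win, "z"])
  }, numeric(1))
}

#' Obstacle clearance of the highest swing
#'
#' Identifies the obstacle-crossing step as the step with the highest swing
#' apex and reports its clearance above the typical swing: apex minus the
#' median apex of all other steps.
#'
#' @inheritParams step_swing_apex
#' @return list: `step` (index into the step sequence), `apex` (m),
#'   `clearance` (m), `completed` (logical: at least 3 steps with finite
#'   apexes).
#' @export
obstacle_clearance <- function(traj, footsteps) {
  apex <- step_swing_apex(traj, footsteps)
  ok <- is.finite(apex)
  if (sum(ok) < 3)
    return(list(step = NA_integer_, apex = NA_real_, clearance = NA_real_,
                completed = FALSE))
  k <- which.max(ifelse(ok, apex, -Inf))
  others <- apex[ok & seq_along(apex) != k]
  list(step = k, apex = apex[k],
       clearance = apex[k] - stats::median(others),
       completed = TRUE)
}
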