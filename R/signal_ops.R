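#' Uniformly sampled scalar time series
#'
#' Lightweight container for a uniformly sampled scalar signal (foot speed,
#' head speed, AP position, ...). Values must be finite and the sampling
#' uniform; time is implicit as `t0 + (0:(n-1))/sample_rate`.
#'
#' @param values numeric vector of samples.
#' @param sample_rate sampling frequency in Hz (> 0).
#' @param t0 time of the first sample in seconds.
#' @param units unit label for the values (e.g. `"m"`, `"m/s"`).
#' @return An object of class `scalar_series`.
#' @export
scalar_series <- function(values, sample_rate, t0 = 0, units = "") {
  stopifnot(is.numeric(values), is.numeric(sample_rate), length(sample_rate) == 1)
  if (sample_rate <= 0) stop("sample_rate must be > 0")
  if (length(values) && any(!is.finite(values)))
    stop("scalar_series values must be finite")
  structure(
    list(values = as.numeric(values), sample_rate = as.numeric(sample_rate),
         t0 = as.numeric(t0), units = units),
    class = "scalar_series"
  )
}

#' @export
print.scalar_series <- function(x, ...) {
  cat(sprintf("<scalar_series> %d samples @ %g Hz, t0 = %g s, units = '%s'\n",
              length(x$values), x$sample_rate, x$t0, x$units))
  invisible(x)
}

#' Time stamps of a scalar series
#' @param s a `scalar_series`.
#' @return numeric vector of sample times in seconds.
#' @export
series_time <- function(s) {
  s$t0 + (seq_along(s$values) - 1L) / s$sample_rate
}

# internal: zero-phase Butterworth on a bare numeric vector.
# Odd-reflection padding at both ends keeps the forward-backward pass free of
# start-up transients (DC gain 1 to ~1e-9 on constants).
zerophase_butter <- function(x, cutoff, fs, order = 4) {
  n <- length(x)
  if (n < 3 * order) stop("series too short for zero-phase filtering (need >= ", 3 * order, " samples)")
  nyq <- fs / 2
  if (cutoff >= 0.9 * nyq) {
    warning(sprintf("lowpass cutoff %g Hz >= 0.9 x Nyquist (%g Hz); clamped to %g Hz",
                    cutoff, nyq, 0.9 * nyq))
    cutoff <- 0.9 * nyq
  }
  bf <- signal::butter(order, cutoff / nyq)
  np <- min(n - 1, max(3 * order, ceiling(9 * fs / cutoff)))
  pre  <- 2 * x[1] - x[(np + 1):2]
  post <- 2 * x[n] - x[(n - 1):(n - np)]
  y <- signal::filtfilt(bf, c(pre, x, post))
  y[(np + 1):(np + n)]
}

# internal: zero-phase Gaussian smoother with the same -3 dB cutoff
# convention as a Butterworth (|H(fc)| = 1/sqrt(2) => sigma_t = 0.1325 / fc).
# Unlike a Butterworth it has a strictly monotone, ringing-free impulse
# response, so smoothing a speed pulse never creates spurious bumps inside
# an adjacent zero-speed plateau; used for all threshold-crossing signals.
gaussian_smooth <- function(x, cutoff, fs) {
  n <- length(x)
  if (n < 3) stop("series too short to smooth")
  sigma <- sqrt(log(2)) / (2 * pi * cutoff) * fs   # in samples
  half <- min(max(1L, ceiling(4 * sigma)), n - 1L)
  k <- stats::dnorm(-half:half, sd = sigma)
  k <- k / sum(k)
  pre  <- 2 * x[1] - x[(half + 1):2]
  post <- 2 * x[n] - x[(n - 1):(n - half)]
  y <- stats::filter(c(pre, x, post), k, sides = 2)
  as.numeric(y[(half + 1):(half + n)])
}

#' Zero-phase low-pass filter
#'
#' Forward-backward (zero-phase) 4th-order Butterworth low-pass. Because the
#' filter is applied in both directions the effective magnitude response is
#' the squared 4th-order response (8th-order roll-off) and symmetric pulses
#' keep their peak location. Requested cutoffs at or above 0.9 x Nyquist are
#' clamped to 0.9 x Nyquist with a warning, since such a digital filter is
#' otherwise unrealizable at the given sampling rate.
#'
#' @param s a [scalar_series()].
#' @param cutoff cutoff frequency in Hz (> 0).
#' @param order filter order per pass (default 4).
#' @return Filtered `scalar_series` with the same sampling.
#' @export
lowpass <- function(s, cutoff, order = 4) {
  stopifnot(inherits(s, "scalar_series"))
  if (cutoff <= 0) stop("cutoff must be > 0")
  y <- zerophase_butter(s$values, cutoff, s$sample_rate, order)
  scalar_series(y, s$sample_rate, s$t0, s$units)
}

#' Numerical time derivative
#'
#' Central differences in the interior, one-sided differences at the ends.
#' Exact for polynomials up to degree 2 at interior samples.
#'
#' @param s a [scalar_series()] with at least 3 samples.
#' @return `scalar_series` of the derivative; units gain a "/s".
#' @export
derivative <- function(s) {
  stopifnot(inherits(s, "scalar_series"))
  x <- s$values
  n <- length(x)
  if (n < 3) stop("derivative needs at least 3 samples")
  dt <- 1 / s$sample_rate
  d <- numeric(n)
  d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / (2 * dt)
  d[1] <- (x[2] - x[1]) / dt
  d[n] <- (x[n] - x[n - 1]) / dt
  units <- if (nzchar(s$units)) paste0(s$units, "/s") else ""
  scalar_series(d, s$sample_rate, s$t0, units)
}

#' Smooth all keypoint coordinates of a trajectory
#'
#' Applies the zero-phase Butterworth [lowpass()] to every coordinate of
#' every keypoint. Used to suppress keypoint jitter ahead of analysis.
#' When the requested cutoff is at or above 0.45 x the sampling rate the
#' data cannot contain such frequencies and the trajectory is returned
#' unchanged (e.g. a 25 Hz request on a 30 Hz stream).
#'
#' @param traj a [kpt_traj()].
#' @param cutoff low-pass cutoff in Hz.
#' @return the smoothed `kpt_traj`.
#' @export
smooth_keypoints <- function(traj, cutoff) {
  stopifnot(inherits(traj, "kpt_traj"))
  if (cutoff >= 0.45 * traj$sample_rate || n_samples(traj) < 12) return(traj)
  out <- traj
  for (k in keypoint_names(traj)) for (ax in 1:3)
    out$positions[, k, ax] <- zerophase_butter(traj$positions[, k, ax],
                                               cutoff, traj$sample_rate)
  out
}

#' Linear resampling to a new rate
#'
#' Linear interpolation onto a uniform grid at `new_rate` spanning the same
#' time interval; the first sample time is preserved.
#'
#' @param s a [scalar_series()].
#' @param new_rate target sampling frequency in Hz (> 0).
#' @return Resampled `scalar_series`.
#' @export
resample_linear <- function(s, new_rate) {
  stopifnot(inherits(s, "scalar_series"))
  if (new_rate <= 0) stop("new_rate must be > 0")
  if (!length(s$values)) stop("cannot resample an empty series")
  t_old <- series_time(s)
  t_end <- t_old[length(t_old)]
  n_new <- floor((t_end - s$t0) * new_rate + 1e-9) + 1L
  t_new <- s$t0 + (seq_len(n_new) - 1L) / new_rate
  y <- stats::approx(t_old, s$values, xout = t_new, rule = 2)$y
  scalar_series(y, new_rate, s$t0, s$units)
}
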