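#' Time-align two systems by cross-correlating summed foot speed
#'
#' The markerless summed AP foot speed (|L| + |R|) is linearly interpolated
#' to the markered system's sample rate and the lag maximizing the
#' normalized cross-correlation is reported. A positive lag means the
#' markerless stream runs behind the markered one; shifting the markerless
#' clock by `-lag` brings the two into agreement.
#'
#' @param sum_speed_ml markerless summed foot-speed [scalar_series()]
#'   (typically 30 Hz).
#' @param sum_speed_mk markered summed foot-speed [scalar_series()]
#'   (typically 240 Hz).
#' @param max_lag largest |lag| searched (s).
#' @param min_peak_corr confidence floor on the correlation peak.
#' @return list (`alignment_result`): `lag` (s), `peak_corr`,
#'   `resampled_rate` (Hz).
#' @export
time_align <- function(sum_speed_ml, sum_speed_mk, max_lag = 2,
                       min_peak_corr = 0.5) {
  stopifnot(inherits(sum_speed_ml, "scalar_series"),
            inherits(sum_speed_mk, "scalar_series"))
  fs <- sum_speed_mk$sample_rate
  ml <- resample_linear(sum_speed_ml, fs)
  a <- ml$values; b <- sum_speed_mk$values
  nlag <- round(max_lag * fs)
  lags <- -nlag:nlag
  r <- vapply(lags, function(k) {
    # overlap of a shifted by k against b
    ia <- max(1, 1 - k):min(length(a), length(b) - k)
    ib <- ia + k
    if (length(ia) < 8) return(-Inf)
    sa <- stats::sd(a[ia]); sb <- stats::sd(b[ib])
    if (sa < 1e-12 || sb < 1e-12) return(0)
    stats::cor(a[ia], b[ib])
  }, numeric(1))
  k <- which.max(r)
  if (!is.finite(r[k]) || r[k] < min_peak_corr)
    stop_low_confidence(sprintf(
      "time alignment: peak correlation %.2f below %.2f", max(r[is.finite(r)], -1),
      min_peak_corr))
  # argmax shift k* satisfies a[i] ~ b[i + k*]; a delayed by L gives k* = -L
  list(lag = -lags[k] / fs, peak_corr = r[k], resampled_rate = fs)
}

#' Shift a trajectory's clock
#'
#' Convenience used after [time_align()]: adds `dt` to the trajectory time
#' base (its `t0`).
#'
#' @param traj a [kpt_traj()].
#' @param dt time shift in seconds.
#' @return the shifted `kpt_traj`.
#' @export
shift_time <- function(traj, dt) {
  traj$t0 <- traj$t0 + dt
  traj
}

#' Spatially register one system onto another
#'
#' Translates `traj_b` so that its left-foot position coincides with
#' `traj_a`'s at the first sample (registration at the start of the walking
#' bout). Both trajectories must be in walkway frames.
#'
#' @param traj_a reference [kpt_traj()].
#' @param traj_b trajectory to translate.
#' @return the translated `traj_b`.
#' @export
spatial_register <- function(traj_a, traj_b) {
  la <- keypoint_xyz(traj_a, heel_name(traj_a, "L"))[1, ]
  lb <- keypoint_xyz(traj_b, heel_name(traj_b, "L"))[1, ]
  off <- la - lb
  out <- traj_b
  for (k in keypoint_names(traj_b))
    out$positions[, k, ] <- sweep(keypoint_xyz(traj_b, k), 2, off, `+`)
  out
}

#' Ordinary least squares with confidence intervals
#'
#' OLS of `y` on `x` with t-distribution confidence intervals (n - 2 df)
#' and the squared Pearson correlation.
#'
#' @param x predictor values.
#' @param y response values (same length).
#' @param confidence confidence level (default 0.95).
#' @return list: `slope`, `intercept`, `slope_ci`, `intercept_ci`
#'   (2-vectors), `r_squared`, `n`.
#' @export
ols_with_ci <- function(x, y, confidence = 0.95) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 pairs")
  if (stats::sd(x) < 1e-14) stop("degenerate fit: x is constant")
  fit <- stats::lm(y ~ x)
  ci <- suppressWarnings(stats::confint(fit, level = confidence))
  co <- stats::coef(fit)
  list(slope = unname(co[2]), intercept = unname(co[1]),
       slope_ci = unname(ci[2, ]), intercept_ci = unname(ci[1, ]),
       r_squared = summary(fit)$r.squared, n = length(x))
}

#' Bland-Altman agreement statistics
#'
#' Differences are taken as `a - b` (first system minus second). Reports
#' the mean difference and the 95% limits of agreement
#' `mean(d) +/- 1.96 sd(d)` (sample SD, n - 1 denominator).
#'
#' @param a,b paired measurements (equal length, n >= 2).
#' @param k limits-of-agreement multiplier (default 1.96).
#' @return list: `mean_diff`, `loa_low`, `loa_high`, `sd_diff`, `n`.
#' @export
bland_altman <- function(a, b, k = 1.96) {
  if (length(a) != length(b)) stop("paired inputs must have equal length")
  if (length(a) < 2) stop("need at least 2 pairs")
  d <- a - b
  m <- mean(d); s <- stats::sd(d)
  list(mean_diff = m, loa_low = m - k * s, loa_high = m + k * s,
       sd_diff = s, n = length(d))
}

#' Pair steps of two systems by midstance time
#'
#' Greedy nearest-midstance-time matching of two footstep-derived step
#' lists within `max_time_gap`. Unmatched steps are reported, never
#' silently dropped.
#'
#' @param steps_a,steps_b [step_metrics()] data frames from time-aligned
#'   trajectories; each needs a `midstance_time`-derived time column, taken
#'   here as the leading footstep's midstance (`t` column added by
#'   [steps_with_times()]; any column named `t` works).
#' @param max_time_gap largest tolerated time difference (s).
#' @return list: `pairs` (data frame with matched indices, times, and both
#'   systems' step length/width), `unmatched_a`, `unmatched_b` (integer
#'   indices).
#' @export
pair_steps <- function(steps_a, steps_b, max_time_gap = 0.3) {
  ta <- steps_a$t; tb <- steps_b$t
  if (is.null(ta) || is.null(tb))
    stop("step tables need a 't' column (see steps_with_times)")
  used_b <- logical(length(tb))
  ia <- integer(); ib <- integer()
  for (i in order(ta)) {
    cand <- which(!used_b)
    if (!length(cand)) break
    j <- cand[which.min(abs(tb[cand] - ta[i]))]
    if (abs(tb[j] - ta[i]) <= max_time_gap) {
      used_b[j] <- TRUE
      ia <- c(ia, i); ib <- c(ib, j)
    }
  }
  ord <- order(ta[ia])
  ia <- ia[ord]; ib <- ib[ord]
  pairs <- data.frame(index_a = ia, index_b = ib,
                      t_a = ta[ia], t_b = tb[ib],
                      step_length_a = steps_a$step_length[ia],
                      step_length_b = steps_b$step_length[ib],
                      step_width_a = steps_a$step_width_signed[ia],
                      step_width_b = steps_b$step_width_signed[ib])
  list(pairs = pairs,
       unmatched_a = setdiff(seq_along(ta), ia),
       unmatched_b = setdiff(seq_along(tb), ib))
}

#' Attach leading-footstep times to a step table
#' @param steps a [step_metrics()] data frame.
#' @param footsteps the footstep data frame the steps came from.
#' @return `steps` with a `t` column (leading footstep midstance time).
#' @export
steps_with_times <- function(steps, footsteps) {
  steps$t <- footsteps$midstance_time[steps$index + 1L]
  steps
}

#' End-to-end two-system agreement validation
#'
#' Reproduces the full marker-vs-markerless comparison: time alignment by
#' cross-correlated summed foot speed, spatial registration at the first
#' left-foot sample, footstep extraction per system, step pairing, and OLS
#' (markered regressed on markerless) plus Bland-Altman
#' (markerless - markered) per metric.
#'
#' @param markerless,markered walkway-frame [kpt_traj()] objects.
#' @param cfg an [event_config()].
#' @param max_time_gap step-pairing window (s).
#' @return list (`validation_report`): `alignment`, `n_pairs`, `unmatched`,
#'   `pairs`, and per-metric `step_length` / `step_width` entries each with
#'   `ols` and `bland_altman` results.
#' @export
compare_systems <- function(markerless, markered, cfg = event_config(),
                            max_time_gap = 0.3) {
  sum_ml <- local({
    a <- foot_speed(markerless, "L", cfg); b <- foot_speed(markerless, "R", cfg)
    scalar_series(a$values + b$values, a$sample_rate, a$t0, "m/s")
  })
  sum_mk <- local({
    a <- foot_speed(markered, "L", cfg); b <- foot_speed(markered, "R", cfg)
    scalar_series(a$values + b$values, a$sample_rate, a$t0, "m/s")
  })
  al <- time_align(sum_ml, sum_mk)
  ml <- shift_time(markerless, -al$lag)
  ml <- spatial_register(markered, ml)

  ev_ml <- find_footsteps(ml, cfg)
  ev_mk <- find_footsteps(markered, cfg)
  st_ml <- steps_with_times(step_metrics(ev_ml$footsteps), ev_ml$footsteps)
  st_mk <- steps_with_times(step_metrics(ev_mk$footsteps), ev_mk$footsteps)
  pr <- pair_steps(st_ml, st_mk, max_time_gap)
  if (nrow(pr$pairs) < 3)
    stop_data_quality("fewer than 3 matched step pairs between the systems")

  agree <- function(a, b) list(
    ols = ols_with_ci(a, b),          # markered regressed on markerless
    bland_altman = bland_altman(a, b) # markerless - markered
  )
  list(alignment = al,
       n_pairs = nrow(pr$pairs),
       unmatched = list(markerless = pr$unmatched_a, markered = pr$unmatched_b),
       pairs = pr$pairs,
       step_length = agree(pr$pairs$step_length_a, pr$pairs$step_length_b),
       step_width = agree(pr$pairs$step_width_a, pr$pairs$step_width_b))
}
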