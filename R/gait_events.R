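#' Event-detection configuration
#'
#' Tunable parameters of stance/bout detection. Defaults carry the
#' measurement constants used throughout the pipeline: stance is any region
#' where low-pass-filtered (3 Hz) AP foot speed stays below 0.15 m/s.
#'
#' @param speed_threshold stance speed threshold (m/s).
#' @param foot_speed_cutoff low-pass cutoff applied to foot and head speed (Hz).
#' @param min_stance minimum stance duration (s); shorter regions are dropped.
#' @param min_swing_gap above-threshold gaps shorter than this are merged into
#'   the surrounding stance (debouncing, s).
#' @param template_cadence,template_speed cadence (steps/s) and steady speed
#'   (m/s) used to synthesize the gait-initiation/termination templates; if
#'   `NULL`, [find_footsteps()] estimates them from the detected stances.
#' @param template_stance_fraction stance fraction assumed by the templates.
#' @param bout_end_margin footsteps whose stance begins up to this long after
#'   the detected bout end are still attributed to the bout (s).
#' @param footstep_location `"stance_mean"` (average heel position over the
#'   stance region, default) or `"midpoint"` (heel position at the midstance
#'   sample).
#' @param min_peak_corr template-match correlation below which bout detection
#'   refuses to answer.
#' @return Object of class `event_config`.
#' @export
event_config <- function(speed_threshold = 0.15, foot_speed_cutoff = 3,
                         min_stance = 0.15, min_swing_gap = 0.10,
                         template_cadence = NULL, template_speed = NULL,
                         template_stance_fraction = 0.6,
                         bout_end_margin = 0.2,
                         footstep_location = c("stance_mean", "midpoint"),
                         min_peak_corr = 0.5) {
  footstep_location <- match.arg(footstep_location)
  vals <- c(speed_threshold, foot_speed_cutoff, min_stance, min_swing_gap,
            template_stance_fraction, bout_end_margin, min_peak_corr)
  if (any(vals <= 0)) stop("all event_config parameters must be positive")
  structure(list(speed_threshold = speed_threshold,
                 foot_speed_cutoff = foot_speed_cutoff,
                 min_stance = min_stance, min_swing_gap = min_swing_gap,
                 template_cadence = template_cadence,
                 template_speed = template_speed,
                 template_stance_fraction = template_stance_fraction,
                 bout_end_margin = bout_end_margin,
                 footstep_location = footstep_location,
                 min_peak_corr = min_peak_corr),
            class = "event_config")
}

# error helpers carrying condition classes used for CLI exit codes
stop_low_confidence <- function(...) {
  stop(structure(class = c("gaitfga_low_confidence", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}
stop_data_quality <- function(...) {
  stop(structure(class = c("gaitfga_data_quality", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

# resolve the heel/foot keypoint of a side across dialects
heel_name <- function(traj, side) {
  long <- if (toupper(side) == "L") "left" else "right"
  for (cand in paste0(long, c("_heel", "_foot")))
    if (cand %in% keypoint_names(traj)) return(cand)
  stop("no heel/foot keypoint for side ", side, " (have: ",
       paste(keypoint_names(traj), collapse = ", "), ")")
}

#' Anterior-posterior foot speed
#'
#' Absolute AP (x) velocity of a heel keypoint, smoothed at
#' `cfg$foot_speed_cutoff` (default 3 Hz) and clamped at zero. The smoother
#' is a zero-phase Gaussian with the Butterworth -3 dB cutoff convention:
#' its monotone, ringing-free response cannot manufacture spurious
#' above-threshold bumps inside a stance plateau, which matters because
#' this signal is consumed by a fixed 0.15 m/s threshold crossing.
#'
#' @param traj a walkway-frame [kpt_traj()].
#' @param side `"L"` or `"R"`.
#' @param cfg an [event_config()].
#' @return a [scalar_series()] in m/s.
#' @export
foot_speed <- function(traj, side, cfg = event_config()) {
  x <- keypoint_series(traj, heel_name(traj, side), "x")
  v <- derivative(x)
  v$values <- pmax(gaussian_smooth(abs(v$values), cfg$foot_speed_cutoff,
                                   v$sample_rate), 0)
  v$units <- "m/s"
  v
}

#' Detect stance intervals from a foot-speed series
#'
#' Maximal regions where the speed stays below `cfg$speed_threshold` are
#' stance candidates. Above-threshold gaps shorter than `cfg$min_swing_gap`
#' are merged away; candidates shorter than `cfg$min_stance` are discarded.
#' The midstance instant is the temporal midpoint of the region and the
#' footstep location is the mean heel position over the region (or the heel
#' position at the midstance sample when
#' `cfg$footstep_location = "midpoint"`).
#'
#' @param speed a [foot_speed()] series.
#' @param traj the trajectory the speed was derived from.
#' @param side `"L"` or `"R"`.
#' @param cfg an [event_config()].
#' @return data frame with one row per stance: `side`, `start`, `end`,
#'   `midstance_time`, `x`, `y`, `z`. Zero rows when no stance is found.
#' @export
detect_stances <- function(speed, traj, side, cfg = event_config()) {
  stopifnot(inherits(speed, "scalar_series"), inherits(traj, "kpt_traj"))
  below <- speed$values < cfg$speed_threshold
  n <- length(below)
  empty <- data.frame(side = character(), start = numeric(), end = numeric(),
                      midstance_time = numeric(), x = numeric(), y = numeric(),
                      z = numeric())
  if (!any(below)) return(empty)
  runs <- rle(below)
  # debounce: flip short above-threshold runs that sit between stance runs
  if (length(runs$lengths) > 2) {
    gap_len <- cfg$min_swing_gap * speed$sample_rate
    interior <- seq_along(runs$values)[-c(1, length(runs$values))]
    flip <- interior[!runs$values[interior] & runs$lengths[interior] < gap_len]
    if (length(flip)) {
      runs$values[flip] <- TRUE
      below <- inverse.rle(runs)
      runs <- rle(below)
    }
  }
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  keep <- runs$values & (runs$lengths >= cfg$min_stance * speed$sample_rate)
  if (!any(keep)) return(empty)
  starts <- starts[keep]; ends <- ends[keep]
  tt <- series_time(speed)
  heel <- keypoint_xyz(traj, heel_name(traj, side))
  out <- lapply(seq_along(starts), function(i) {
    idx <- starts[i]:ends[i]
    mid_t <- (tt[starts[i]] + tt[ends[i]]) / 2
    loc <- if (cfg$footstep_location == "stance_mean") {
      colMeans(heel[idx, , drop = FALSE])
    } else {
      heel[idx[which.min(abs(tt[idx] - mid_t))], ]
    }
    data.frame(side = side, start = tt[starts[i]], end = tt[ends[i]],
               midstance_time = mid_t, x = loc[["x"]], y = loc[["y"]], z = loc[["z"]])
  })
  do.call(rbind, out)
}

#' Gait-initiation and -termination templates
#'
#' Builds the summed-|AP foot speed| profile of a two-step gait initiation:
#' a 0.5 s quiet plateau followed by a first swing pulse advancing one step
#' length and a second advancing two (the steady swing amplitude). The
#' termination template is the time-reversed initiation template. Template
#' length is `2 / cadence + 0.5` s.
#'
#' @param cadence steps per second.
#' @param steady_speed steady walking speed (m/s); one step length is
#'   `steady_speed / cadence`.
#' @param fs sampling rate of the series the template will be correlated
#'   with (Hz).
#' @param stance_fraction stance fraction of the assumed gait (default 0.6).
#' @return list with `init` and `term` ([scalar_series()]), `onset_offset`
#'   (time of the first swing onset inside `init`, s) and `term_offset`
#'   (time of the last swing offset inside `term`, s).
#' @export
make_templates <- function(cadence, steady_speed, fs, stance_fraction = 0.6) {
  stopifnot(cadence > 0, steady_speed > 0, fs > 0)
  Ts <- 1 / cadence
  L <- steady_speed / cadence
  sw_dur <- (1 - stance_fraction) * 2 * Ts
  len <- 2 / cadence + 0.5
  nT <- round(len * fs)
  t <- (seq_len(nT) - 1) / fs
  pulse <- function(onset, adv) {
    u <- (t - onset) / sw_dur
    v <- numeric(nT)
    inside <- u > 0 & u < 1
    v[inside] <- adv * pi / (2 * sw_dur) * sin(pi * u[inside])
    v
  }
  init <- pulse(0.5, L) + pulse(0.5 + Ts, 2 * L)
  list(init = scalar_series(init, fs, 0, "m/s"),
       term = scalar_series(rev(init), fs, 0, "m/s"),
       onset_offset = 0.5,
       term_offset = len - 0.5)
}

#' Normalized cross-correlation of a template against a signal
#'
#' Pearson correlation between the template and every same-length window of
#' the signal (valid placements only). Windows with (near-)zero variance get
#' correlation 0.
#'
#' @param x numeric signal.
#' @param template numeric template, not longer than `x`.
#' @return list with `lag` (0-based window start offsets, samples) and `r`.
#' @export
norm_xcorr <- function(x, template) {
  n <- length(x); m <- length(template)
  if (m > n) stop("template longer than signal")
  if (stats::sd(template) == 0) stop("template has zero variance")
  cx <- c(0, cumsum(x)); cx2 <- c(0, cumsum(x^2))
  win_sum <- cx[(m + 1):(n + 1)] - cx[1:(n - m + 1)]
  win_sum2 <- cx2[(m + 1):(n + 1)] - cx2[1:(n - m + 1)]
  cross <- as.numeric(stats::convolve(x, template, conj = TRUE, type = "filter"))
  st <- sum(template); st2 <- sum(template^2)
  num <- cross - win_sum * st / m
  den <- sqrt(pmax(win_sum2 - win_sum^2 / m, 0) * (st2 - st^2 / m))
  r <- ifelse(den > 1e-12 * m, num / den, 0)
  list(lag = 0:(n - m), r = r)
}

#' Detect a walking bout from summed foot speed
#'
#' Cross-correlates the summed left+right AP foot speed with a
#' gait-initiation template; the bout start is read off the correlation
#' maximum (aligned to the template's first swing onset). A time-reversed
#' gait-termination template is matched the same way, restricted to
#' placements after the start.
#'
#' @param sum_speed [scalar_series()]: `|L| + |R|` AP foot speed.
#' @param cfg an [event_config()] with `template_cadence` and
#'   `template_speed` set, or an explicit `templates` argument.
#' @param templates optional result of [make_templates()].
#' @return list (`bout_window`): `t_start`, `t_end`, `corr_start`,
#'   `corr_end`.
#' @export
detect_bout <- function(sum_speed, cfg = event_config(), templates = NULL) {
  stopifnot(inherits(sum_speed, "scalar_series"))
  if (is.null(templates)) {
    if (is.null(cfg$template_cadence) || is.null(cfg$template_speed))
      stop("detect_bout needs templates, or template_cadence/template_speed in cfg")
    templates <- make_templates(cfg$template_cadence, cfg$template_speed,
                                sum_speed$sample_rate, cfg$template_stance_fraction)
  }
  fs <- sum_speed$sample_rate
  # match the template through the same measurement smoother as the signal
  ti <- gaussian_smooth(templates$init$values, cfg$foot_speed_cutoff, fs)
  te <- gaussian_smooth(templates$term$values, cfg$foot_speed_cutoff, fs)
  x <- sum_speed$values
  cc_i <- norm_xcorr(x, ti)
  k_i <- which.max(cc_i$r)
  if (cc_i$r[k_i] < cfg$min_peak_corr)
    stop_low_confidence(sprintf(
      "gait-initiation template: peak correlation %.2f below %.2f - no walking bout found",
      cc_i$r[k_i], cfg$min_peak_corr))
  t_start <- sum_speed$t0 + cc_i$lag[k_i] / fs + templates$onset_offset

  cc_t <- norm_xcorr(x, te)
  t_end_cand <- sum_speed$t0 + cc_t$lag / fs + templates$term_offset
  ok <- t_end_cand > t_start
  if (!any(ok))
    stop_low_confidence("gait-termination template: no placement after the bout start")
  k_t <- which(ok)[which.max(cc_t$r[ok])]
  if (cc_t$r[k_t] < cfg$min_peak_corr)
    stop_low_confidence(sprintf(
      "gait-termination template: peak correlation %.2f below %.2f",
      cc_t$r[k_t], cfg$min_peak_corr))
  list(t_start = t_start, t_end = t_end_cand[k_t],
       corr_start = cc_i$r[k_i], corr_end = cc_t$r[k_t])
}

#' Full footstep extraction for one trial
#'
#' Runs the event pipeline on a walkway-frame trajectory: per-side AP foot
#' speed, stance detection over the whole series, bout detection from the
#' summed speed, and attribution of stances to the bout. Stances that begin
#' before (or at) the bout start are the initial quiet standing and are
#' dropped; stances beginning up to `cfg$bout_end_margin` after the bout end
#' (the final foot placement, whose stance extends into quiet standing) are
#' kept. When the template parameters are not set in `cfg` they are
#' estimated from the detected stances (cadence from the median midstance
#' interval, speed from the median AP displacement per step).
#'
#' @param traj a walkway-frame [kpt_traj()].
#' @param cfg an [event_config()].
#' @return list: `footsteps` (time-ordered data frame as [detect_stances()]),
#'   `bout` (from [detect_bout()]), `sum_speed`, per-side `stances`, and
#'   `flags` (character vector of data-quality flags, e.g. broken L/R
#'   alternation).
#' @export
find_footsteps <- function(traj, cfg = event_config()) {
  spL <- foot_speed(traj, "L", cfg)
  spR <- foot_speed(traj, "R", cfg)
  stL <- detect_stances(spL, traj, "L", cfg)
  stR <- detect_stances(spR, traj, "R", cfg)
  stances <- rbind(stL, stR)
  stances <- stances[order(stances$midstance_time), , drop = FALSE]

  if (is.null(cfg$template_cadence) || is.null(cfg$template_speed)) {
    if (nrow(stances) < 4)
      stop_data_quality("too few stances (", nrow(stances),
                        ") to estimate gait templates")
    dt <- stats::median(diff(sort(c(stL$midstance_time, stR$midstance_time))))
    dx <- stats::median(abs(diff(stances$x)))
    if (!is.finite(dt) || dt <= 0 || dx <= 0)
      stop_data_quality("could not estimate cadence/speed from stances")
    cfg$template_cadence <- 1 / dt
    cfg$template_speed <- dx / dt
  }
  sum_speed <- scalar_series(spL$values + spR$values, spL$sample_rate, spL$t0, "m/s")
  bout <- detect_bout(sum_speed, cfg)

  keep <- stances$start > bout$t_start &
    stances$start <= bout$t_end + cfg$bout_end_margin
  fs <- stances[keep, , drop = FALSE]
  rownames(fs) <- NULL
  flags <- character()
  if (nrow(fs) >= 2 && any(fs$side[-1] == fs$side[-nrow(fs)]))
    flags <- c(flags, "left/right stances do not alternate in time")
  if (!nrow(fs)) flags <- c(flags, "no footsteps inside the detected bout")
  list(footsteps = fs, bout = bout, sum_speed = sum_speed,
       stances = list(L = stL, R = stR), flags = flags)
}
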