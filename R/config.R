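#' Flat analysis configuration
#'
#' One flat, documented key set covering event detection, FGA scoring
#' thresholds, walkway-frame fitting and I/O dialect. Every measurement
#' constant of the pipeline lives here with its default; unknown keys are
#' rejected. Reports embed the resolved configuration.
#'
#' Keys and defaults:
#' \describe{
#'   \item{speed_threshold (0.15 m/s)}{stance foot-speed threshold.}
#'   \item{foot_speed_cutoff (3 Hz)}{low-pass cutoff for foot/head speed.}
#'   \item{keypoint_smoothing_cutoff (25 Hz)}{keypoint position low-pass;
#'     clamped to 0.9 x Nyquist when unrealizable at the data's rate.}
#'   \item{min_stance (0.15 s), min_swing_gap (0.10 s)}{stance debouncing.}
#'   \item{template_cadence, template_speed (NA = estimate)}{bout-template
#'     gait parameters.}
#'   \item{bout_end_margin (0.2 s)}{terminal footstep attribution margin.}
#'   \item{footstep_location ("stance_mean")}{or "midpoint".}
#'   \item{forward_dist (5 m), right_dist (1 m)}{calibration distances for
#'     walkway-frame fitting.}
#'   \item{walkway_halfwidth (0.1524 m)}{half the marked walkway width.}
#'   \item{lateral_limit (0.1524 m)}{lateral placement limit for scoring.}
#'   \item{cond2_score3_min (1.25), cond2_score2_min (1.10),
#'     cond2_score1_min (1.05)}{Condition-2 speed-ratio bins.}
#'   \item{cond34_tight_lo (0.95), cond34_tight_hi (1.05), cond34_mid_lo
#'     (0.90), cond34_mid_hi (1.10), cond34_floor (0.75)}{Condition-3/4
#'     bands.}
#'   \item{cond5_fast (3 s), cond5_slow (4.5 s)}{pivot-turn cutpoints.}
#'   \item{cond6_speed_floor (0.75), clearance_high (0.10 m)}{Condition-6.}
#'   \item{v_turn (0.2 m/s)}{pivot-turn bracketing speed.}
#'   \item{dialect ("markerless")}{input CSV dialect.}
#' }
#'
#' @param ... key = value overrides of the defaults above.
#' @return Object of class `analysis_config` (a named list).
#' @export
analysis_config <- function(...) {
  defaults <- list(
    speed_threshold = 0.15, foot_speed_cutoff = 3,
    keypoint_smoothing_cutoff = 25,
    min_stance = 0.15, min_swing_gap = 0.10,
    template_cadence = NA_real_, template_speed = NA_real_,
    template_stance_fraction = 0.6, bout_end_margin = 0.2,
    footstep_location = "stance_mean", min_peak_corr = 0.5,
    forward_dist = 5.0, right_dist = 1.0,
    walkway_halfwidth = 0.1524, lateral_limit = 0.1524,
    cond2_score3_min = 1.25, cond2_score2_min = 1.10, cond2_score1_min = 1.05,
    cond34_tight_lo = 0.95, cond34_tight_hi = 1.05,
    cond34_mid_lo = 0.90, cond34_mid_hi = 1.10, cond34_floor = 0.75,
    cond5_fast = 3, cond5_slow = 4.5,
    cond6_speed_floor = 0.75, clearance_high = 0.10,
    v_turn = 0.2, dialect = "markerless")
  over <- list(...)
  if (length(over) == 1 && is.list(over[[1]]) && is.null(names(over)))
    over <- over[[1]]
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown))
    stop("unknown analysis_config key(s): ", paste(unknown, collapse = ", "))
  defaults[names(over)] <- over
  structure(defaults, class = "analysis_config")
}

#' @rdname analysis_config
#' @param cfg an `analysis_config`.
#' @export
as_event_config <- function(cfg) {
  event_config(
    speed_threshold = cfg$speed_threshold,
    foot_speed_cutoff = cfg$foot_speed_cutoff,
    min_stance = cfg$min_stance, min_swing_gap = cfg$min_swing_gap,
    template_cadence = if (is.na(cfg$template_cadence)) NULL else cfg$template_cadence,
    template_speed = if (is.na(cfg$template_speed)) NULL else cfg$template_speed,
    template_stance_fraction = cfg$template_stance_fraction,
    bout_end_margin = cfg$bout_end_margin,
    footstep_location = cfg$footstep_location,
    min_peak_corr = cfg$min_peak_corr)
}

#' @rdname analysis_config
#' @export
as_scoring_thresholds <- function(cfg) {
  scoring_thresholds(
    cond2 = c(score3_min = cfg$cond2_score3_min,
              score2_min = cfg$cond2_score2_min,
              score1_min = cfg$cond2_score1_min),
    cond34 = c(tight_lo = cfg$cond34_tight_lo, tight_hi = cfg$cond34_tight_hi,
               mid_lo = cfg$cond34_mid_lo, mid_hi = cfg$cond34_mid_hi,
               floor = cfg$cond34_floor),
    lateral_limit = cfg$lateral_limit,
    cond5 = c(fast = cfg$cond5_fast, slow = cfg$cond5_slow),
    cond6_speed_floor = cfg$cond6_speed_floor,
    clearance_high = cfg$clearance_high)
}

#' Read a flat key=value configuration file
#'
#' Lines of the form `key = value`; `#` starts a comment. Values are parsed
#' as numbers where possible, otherwise kept as strings.
#'
#' @param path configuration file.
#' @return an [analysis_config()].
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- lengths(kv) != 2
  if (any(bad)) stop("malformed config line: ", lines[bad][1])
  vals <- lapply(kv, function(p) {
    v <- suppressWarnings(as.numeric(p[2]))
    if (is.na(v) && p[2] != "NA") p[2] else v
  })
  names(vals) <- vapply(kv, `[`, "", 1)
  analysis_config(vals)
}
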