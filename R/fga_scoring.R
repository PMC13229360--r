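#' FGA scoring thresholds
#'
#' Threshold set applied by the automated scorers for FGA Conditions 2-6.
#' All speed thresholds are expressed as ratios to the Condition-1 ("Gait
#' Level Surface") baseline speed, where 1.00 is the baseline itself.
#' Every value is editable; reports embed the thresholds actually used.
#'
#' Interval-endpoint convention: printed score bins share endpoints
#' (e.g. 105%% closes the score-1 bin and opens the score-2 bin), so bins
#' are applied highest-score-first with inclusive bounds on the
#' higher-score bin; each endpoint therefore maps to exactly one score.
#'
#' @param cond2 named vector: minimum speed ratios opening scores 3, 2, 1
#'   for the fast-walk condition.
#' @param cond34 named vector: the tight ([0.95, 1.05]) and mid
#'   ([0.90, 1.10]) max-speed bands and the 0.75 floor for head-turn
#'   conditions.
#' @param lateral_limit maximum tolerated lateral footstep deviation outside
#'   the walkway (m; default 0.1524 = 15.24 cm - half of it each side of a
#'   30.48 cm walkway edge).
#' @param cond5 named vector: turn-time cutpoints (s): below `fast` scores
#'   3, up to `slow` scores 2, beyond it 1.
#' @param cond6_speed_floor obstacle-crossing speed ratio at or below which
#'   the score is 1.
#' @param clearance_high swing-apex clearance (m) above the typical swing
#'   that counts as "high obstacle clearance".
#' @return Object of class `scoring_thresholds`.
#' @export
scoring_thresholds <- function(cond2 = c(score3_min = 1.25, score2_min = 1.10,
                                         score1_min = 1.05),
                               cond34 = c(tight_lo = 0.95, tight_hi = 1.05,
                                          mid_lo = 0.90, mid_hi = 1.10,
                                          floor = 0.75),
                               lateral_limit = 0.1524,
                               cond5 = c(fast = 3, slow = 4.5),
                               cond6_speed_floor = 0.75,
                               clearance_high = 0.10) {
  stopifnot(all(cond2 > 0), all(cond34 > 0), lateral_limit > 0,
            all(cond5 > 0), cond5[["fast"]] < cond5[["slow"]],
            cond6_speed_floor > 0, clearance_high > 0)
  structure(list(cond2 = cond2, cond34 = cond34, lateral_limit = lateral_limit,
                 cond5 = cond5, cond6_speed_floor = cond6_speed_floor,
                 clearance_high = clearance_high),
            class = "scoring_thresholds")
}

condition_result <- function(condition_id, score, ratio = NA_real_,
                             rule_fired = "", completed = TRUE, metrics = NULL) {
  structure(list(condition_id = condition_id, score = score,
                 ratio_to_baseline = ratio, rule_fired = rule_fired,
                 completed = completed, metrics = metrics),
            class = "condition_result")
}

#' @export
print.condition_result <- function(x, ...) {
  cat(sprintf("FGA condition %s: score %s (%s)\n", x$condition_id,
              if (is.na(x$score)) "unscored" else x$score, x$rule_fired))
  invisible(x)
}

#' Score FGA Condition 2 (Change in Gait Speed)
#'
#' Speed-change scoring relative to Condition 1: score 3 for a speed ratio
#' above 125% of baseline, 2 within [110%, 125%], 1 within [105%, 110%),
#' 0 for no increase beyond 105%.
#'
#' @param mean_speed_fast mean speed of the fast-walk bout (m/s).
#' @param baseline Condition-1 mean speed (m/s, > 0).
#' @param th a [scoring_thresholds()].
#' @return a `condition_result` with integer `score` 0-3.
#' @export
score_condition2 <- function(mean_speed_fast, baseline, th = scoring_thresholds()) {
  if (!is.finite(baseline) || baseline <= 0) stop("baseline speed must be > 0")
  r <- mean_speed_fast / baseline
  b <- th$cond2
  if (r > b[["score3_min"]]) {
    condition_result(2L, 3L, r, sprintf("speed ratio %.3f > %.2f", r, b[["score3_min"]]))
  } else if (r >= b[["score2_min"]]) {
    condition_result(2L, 2L, r, sprintf("speed ratio %.3f in [%.2f, %.2f]",
                                        r, b[["score2_min"]], b[["score3_min"]]))
  } else if (r >= b[["score1_min"]]) {
    condition_result(2L, 1L, r, sprintf("speed ratio %.3f in [%.2f, %.2f)",
                                        r, b[["score1_min"]], b[["score2_min"]]))
  } else {
    condition_result(2L, 0L, r, sprintf("no speed increase beyond %.2f (ratio %.3f)",
                                        b[["score1_min"]], r))
  }
}

#' Score FGA Conditions 3/4 (Gait with Horizontal/Vertical Head Turns)
#'
#' Maximum-speed scoring relative to Condition 1 combined with the lateral
#' placement rule: score 3 for a ratio within [95%, 105%] staying inside
#' the lateral limit, 2 within [90%, 110%] inside the limit, 1 within
#' [75%, 90%) - or for any completed trial whose lateral deviation exceeds
#' the limit (the deviation caps the score at 1) - and 0 below 75%.
#'
#' @param max_speed maximum |head speed| of the trial (m/s).
#' @param baseline Condition-1 mean speed (m/s, > 0).
#' @param max_lateral maximum lateral footstep deviation outside the
#'   walkway (m, >= 0).
#' @param condition_id 3 or 4 (label only).
#' @param th a [scoring_thresholds()].
#' @return a `condition_result`.
#' @export
score_condition34 <- function(max_speed, baseline, max_lateral,
                              condition_id = 3L, th = scoring_thresholds()) {
  if (!is.finite(baseline) || baseline <= 0) stop("baseline speed must be > 0")
  r <- max_speed / baseline
  b <- th$cond34
  lat_ok <- max_lateral <= th$lateral_limit
  if (r < b[["floor"]]) {
    condition_result(condition_id, 0L, r,
                     sprintf("speed ratio %.3f < %.2f", r, b[["floor"]]))
  } else if (r >= b[["tight_lo"]] && r <= b[["tight_hi"]] && lat_ok) {
    condition_result(condition_id, 3L, r,
                     sprintf("speed ratio %.3f in [%.2f, %.2f], lateral within limit",
                             r, b[["tight_lo"]], b[["tight_hi"]]))
  } else if (r >= b[["mid_lo"]] && r <= b[["mid_hi"]] && lat_ok) {
    condition_result(condition_id, 2L, r,
                     sprintf("speed ratio %.3f in [%.2f, %.2f], lateral within limit",
                             r, b[["mid_lo"]], b[["mid_hi"]]))
  } else if (!lat_ok && r >= b[["mid_lo"]] && r <= b[["mid_hi"]]) {
    condition_result(condition_id, 1L, r,
                     sprintf("lateral deviation %.3f m beyond %.4f m caps the score at 1",
                             max_lateral, th$lateral_limit))
  } else {
    condition_result(condition_id, 1L, r,
                     sprintf("speed ratio %.3f outside [%.2f, %.2f] but >= %.2f",
                             r, b[["mid_lo"]], b[["mid_hi"]], b[["floor"]]))
  }
}

#' Measure the pivot-turn duration from head kinematics
#'
#' The turn is located at the global maximum of the AP head position. Its
#' start is the last instant before the maximum at which the signed head
#' speed is still at least `+v_turn`; its end is the first instant after
#' the maximum at which the speed has fallen to `-v_turn`. The turn is
#' incomplete when either crossing is missing (e.g. a monotone forward walk
#' never reverses).
#'
#' @param traj a walkway-frame [kpt_traj()] of a pivot trial.
#' @param v_turn speed threshold bracketing the turn (m/s, default 0.2).
#' @param cutoff head-speed low-pass cutoff (Hz).
#' @return list: `duration` (s, `NA` when incomplete), `completed`,
#'   `t_start`, `t_end`, `t_apex`.
#' @export
detect_turn_duration <- function(traj, v_turn = 0.2, cutoff = 3) {
  kp <- keypoint_names(traj)
  heads <- intersect(c("left_ear", "right_ear", "nose", "head"), kp)
  if (!length(heads)) stop("no head keypoints present")
  xs <- sapply(heads, function(k) keypoint_xyz(traj, k)[, "x"])
  x <- if (is.matrix(xs)) rowMeans(xs) else xs
  v <- head_speed(traj, cutoff)
  tt <- series_time(v)
  i_max <- which.max(x)
  incomplete <- list(duration = NA_real_, completed = FALSE,
                     t_start = NA_real_, t_end = NA_real_, t_apex = tt[i_max])
  if (i_max <= 1 || i_max >= length(x)) return(incomplete)
  before <- which(v$values[seq_len(i_max)] >= v_turn)
  after <- which(v$values[i_max:length(x)] <= -v_turn)
  if (!length(before) || !length(after)) return(incomplete)
  t_start <- tt[max(before)]
  t_end <- tt[i_max + min(after) - 1L]
  list(duration = t_end - t_start, completed = TRUE,
       t_start = t_start, t_end = t_end, t_apex = tt[i_max])
}

#' Score FGA Condition 5 (Gait and Pivot Turn)
#'
#' Turn-time scoring: 3 for a completed turn in under 3 s, 2 when the turn
#' took 3 s or longer, 1 when it took longer than 4.5 s, 0 when the turn
#' was not completed.
#'
#' @param duration measured turn duration (s).
#' @param completed logical from [detect_turn_duration()].
#' @param th a [scoring_thresholds()].
#' @return a `condition_result`.
#' @export
score_condition5 <- function(duration, completed, th = scoring_thresholds()) {
  if (!completed)
    return(condition_result(5L, 0L, rule_fired = "turn not completed",
                            completed = FALSE))
  if (!is.finite(duration) || duration < 0) stop("turn duration must be >= 0")
  cp <- th$cond5
  if (duration < cp[["fast"]]) {
    condition_result(5L, 3L, rule_fired = sprintf("turn in %.2f s < %.1f s",
                                                  duration, cp[["fast"]]))
  } else if (duration <= cp[["slow"]]) {
    condition_result(5L, 2L, rule_fired = sprintf("turn took %.2f s (>= %.1f s)",
                                                  duration, cp[["fast"]]))
  } else {
    condition_result(5L, 1L, rule_fired = sprintf("turn took %.2f s (> %.1f s)",
                                                  duration, cp[["slow"]]))
  }
}

#' Score FGA Condition 6 (Step Over Obstacle)
#'
#' Clearance/speed scoring: 3 for a high-clearance crossing at more than
#' 75% of baseline speed, 2 for a lower crossing at more than 75%, 1 for a
#' crossing at 75% of baseline or slower, 0 for an incomplete crossing.
#'
#' @param clearance swing-apex clearance of the obstacle step above the
#'   typical swing apex (m).
#' @param mean_speed mean speed of the crossing bout (m/s).
#' @param baseline Condition-1 mean speed (m/s, > 0).
#' @param completed logical: was the crossing completed.
#' @param th a [scoring_thresholds()].
#' @return a `condition_result`.
#' @export
score_condition6 <- function(clearance, mean_speed, baseline, completed = TRUE,
                             th = scoring_thresholds()) {
  if (!is.finite(baseline) || baseline <= 0) stop("baseline speed must be > 0")
  if (!completed)
    return(condition_result(6L, 0L, rule_fired = "crossing not completed",
                            completed = FALSE))
  r <- mean_speed / baseline
  if (r <= th$cond6_speed_floor) {
    condition_result(6L, 1L, r, sprintf("crossing speed ratio %.3f <= %.2f",
                                        r, th$cond6_speed_floor))
  } else if (clearance >= th$clearance_high) {
    condition_result(6L, 3L, r, sprintf("high clearance (%.3f m >= %.2f m), speed ratio %.3f",
                                        clearance, th$clearance_high, r))
  } else {
    condition_result(6L, 2L, r, sprintf("low clearance (%.3f m < %.2f m), speed ratio %.3f",
                                        clearance, th$clearance_high, r))
  }
}

.fga_condition_names <- c(
  "Gait Level Surface", "Change in Gait Speed", "Gait with Horizontal Head Turns",
  "Gait with Vertical Head Turns", "Gait and Pivot Turn", "Step Over Obstacle",
  "Gait with Narrow Base of Support", "Gait with Eyes Closed",
  "Ambulating Backwards", "Steps")

#' Analyze one walking trial
#'
#' Composition of the event and spatiotemporal stages: footstep detection,
#' step metrics, head speed and the bout summary.
#'
#' @param traj a walkway-frame [kpt_traj()].
#' @param cfg an [event_config()].
#' @param walkway_halfwidth half the marked walkway width (m).
#' @return list: `footsteps`, `steps`, `bout`, `head_speed`, `summary`,
#'   `flags`.
#' @export
analyze_trial <- function(traj, cfg = event_config(), walkway_halfwidth = 0.1524) {
  ev <- find_footsteps(traj, cfg)
  steps <- step_metrics(ev$footsteps)
  hs <- head_speed(traj, cfg$foot_speed_cutoff)
  summ <- bout_summary(steps, ev$footsteps, hs, ev$bout, walkway_halfwidth)
  list(footsteps = ev$footsteps, steps = steps, bout = ev$bout,
       head_speed = hs, summary = summ, flags = ev$flags)
}

#' Build a full FGA report from a session of trials
#'
#' Runs the analysis pipeline on every trial, scores Conditions 2-6 against
#' the Condition-1 baseline (mean head speed over the bout, averaged over
#' baseline repetitions) and reports metrics without a score for Conditions
#' 1 and 7-10. With repeated trials per condition, each repetition is
#' scored and the condition carries the per-repetition scores plus their
#' median. A trial whose analysis fails yields a flagged, unscored result
#' rather than an error.
#'
#' @param session named list: names are condition ids `"1"` .. `"10"`,
#'   values a [kpt_traj()] or a list of repetitions.
#' @param th a [scoring_thresholds()].
#' @param cfg an [event_config()].
#' @param subject optional subject metadata (list or character).
#' @return Object of class `fga_report`.
#' @export
build_fga_report <- function(session, th = scoring_thresholds(),
                             cfg = event_config(), subject = NULL) {
  if (!("1" %in% names(session)))
    stop("Condition-1 (baseline) trial is required to define the reference speed")
  as_reps <- function(x) if (inherits(x, "kpt_traj")) list(x) else x

  analyses <- lapply(session, function(trial)
    lapply(as_reps(trial), function(traj)
      tryCatch(list(ok = TRUE, traj = traj,
                    res = analyze_trial(traj, cfg, th$lateral_limit)),
               error = function(e) list(ok = FALSE, traj = traj,
                                        error = conditionMessage(e)))))
  base_reps <- analyses[["1"]]
  base_speeds <- vapply(base_reps, function(a)
    if (a$ok) a$res$summary$mean_speed else NA_real_, numeric(1))
  base_max <- vapply(base_reps, function(a)
    if (a$ok) a$res$summary$max_speed else NA_real_, numeric(1))
  baseline <- mean(base_speeds, na.rm = TRUE)
  # conditions 3/4 compare maximum speed like-for-like, against the
  # baseline's maximum rather than its mean
  baseline_max <- mean(base_max, na.rm = TRUE)
  if (!is.finite(baseline) || baseline <= 0)
    stop("could not establish a Condition-1 baseline speed")

  conditions <- lapply(names(analyses), function(id) {
    cid <- as.integer(id)
    reps <- lapply(analyses[[id]], function(a) {
      if (!a$ok)
        return(list(score = NA_integer_, completed = FALSE,
                    rule_fired = paste("analysis failed:", a$error),
                    metrics = NULL))
      s <- a$res$summary
      r <- switch(as.character(cid),
        "2" = score_condition2(s$mean_speed, baseline, th),
        "3" = score_condition34(s$max_speed, baseline_max, s$max_lateral_placement, 3L, th),
        "4" = score_condition34(s$max_speed, baseline_max, s$max_lateral_placement, 4L, th),
        "5" = {
          turn <- detect_turn_duration(a$traj, cutoff = cfg$foot_speed_cutoff)
          score_condition5(turn$duration, turn$completed, th)
        },
        "6" = {
          cl <- obstacle_clearance(a$traj, a$res$footsteps)
          score_condition6(cl$clearance, s$mean_speed, baseline, cl$completed, th)
        },
        condition_result(cid, NA_integer_, s$mean_speed / baseline,
                         "metrics only; no automated scoring rule"))
      list(score = r$score, completed = r$completed, rule_fired = r$rule_fired,
           ratio_to_baseline = r$ratio_to_baseline,
           metrics = s[c("duration", "mean_speed", "max_speed",
                         "max_lateral_placement", "max_step_width",
                         "mean_step_width", "n_steps")])
    })
    scores <- vapply(reps, function(r)
      if (is.null(r$score) || is.na(r$score)) NA_real_ else as.numeric(r$score),
      numeric(1))
    list(condition_id = cid, name = .fga_condition_names[cid],
         scores = scores,
         median_score = if (all(is.na(scores))) NA_real_
                        else stats::median(scores, na.rm = TRUE),
         repetitions = reps)
  })
  names(conditions) <- names(analyses)

  structure(list(subject = subject,
                 software = paste("gaitfga", as.character(utils::packageVersion("gaitfga"))),
                 created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                 baseline_speed = baseline,
                 baseline_max_speed = baseline_max,
                 thresholds = unclass(th),
                 conditions = conditions),
            class = "fga_report")
}

#' @export
print.fga_report <- function(x, ...) {
  cat("<fga_report> baseline speed:", sprintf("%.3f m/s", x$baseline_speed), "\n")
  for (cond in x$conditions) {
    ms <- suppressWarnings(as.numeric(cond$median_score))
    cat(sprintf("  %2d %-33s %s\n", cond$condition_id, cond$name,
                if (length(ms) != 1 || is.na(ms)) "unscored"
                else sprintf("score %g", ms)))
  }
  invisible(x)
}

#' Serialize / deserialize an FGA report as JSON
#' @param report an `fga_report`.
#' @param path JSON file.
#' @return `read_fga_report()` returns the `fga_report`;
#'   `write_fga_report()` the path, invisibly.
#' @export
write_fga_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_fga_report
#' @export
read_fga_report <- function(path) {
  r <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  structure(r, class = "fga_report")
}
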