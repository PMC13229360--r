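#' Keypoint trajectory container
#'
#' A set of named 3D keypoint trajectories sharing one uniform time base.
#' Coordinates follow the walkway convention used throughout the package:
#' x = anterior-posterior (AP, + forward along the walkway once a walkway
#' frame has been applied), y = mediolateral (ML, + toward the subject's
#' left), z = up. Units are meters.
#'
#' @param positions numeric array `[n_samples, n_keypoints, 3]`; the keypoint
#'   dimension must carry dimnames, the axis dimension is `c("x","y","z")`.
#' @param sample_rate sampling frequency in Hz.
#' @param t0 time of the first sample (s).
#' @param frame_tag `"raw"` (as captured) or `"walkway"` (after
#'   [apply_frame()] or simulator output, which is constructed directly in
#'   walkway coordinates).
#' @return Object of class `kpt_traj`.
#' @export
kpt_traj <- function(positions, sample_rate, t0 = 0, frame_tag = c("raw", "walkway")) {
  frame_tag <- match.arg(frame_tag)
  stopifnot(is.array(positions), length(dim(positions)) == 3, dim(positions)[3] == 3)
  if (is.null(dimnames(positions)[[2]]))
    stop("positions must carry keypoint names on dimension 2")
  if (sample_rate <= 0) stop("sample_rate must be > 0")
  dimnames(positions)[[3]] <- c("x", "y", "z")
  structure(
    list(positions = positions, sample_rate = as.numeric(sample_rate),
         t0 = as.numeric(t0), frame_tag = frame_tag),
    class = "kpt_traj"
  )
}

#' @export
print.kpt_traj <- function(x, ...) {
  cat(sprintf("<kpt_traj> %d samples @ %g Hz (%.2f s), %d keypoints [%s], frame = %s\n",
              n_samples(x), x$sample_rate, n_samples(x) / x$sample_rate,
              length(keypoint_names(x)), paste(keypoint_names(x), collapse = ", "),
              x$frame_tag))
  invisible(x)
}

#' @rdname kpt_traj
#' @param traj a `kpt_traj`.
#' @export
keypoint_names <- function(traj) dimnames(traj$positions)[[2]]

#' @rdname kpt_traj
#' @export
n_samples <- function(traj) dim(traj$positions)[1]

#' @rdname kpt_traj
#' @export
traj_time <- function(traj) traj$t0 + (seq_len(n_samples(traj)) - 1L) / traj$sample_rate

#' Extract one keypoint track
#' @param traj a [kpt_traj()].
#' @param name keypoint name.
#' @return `n x 3` matrix of positions (columns x, y, z).
#' @export
keypoint_xyz <- function(traj, name) {
  if (!name %in% keypoint_names(traj))
    stop("keypoint '", name, "' not present (have: ",
         paste(keypoint_names(traj), collapse = ", "), ")")
  p <- traj$positions[, name, , drop = FALSE]
  dim(p) <- c(dim(p)[1], 3)
  colnames(p) <- c("x", "y", "z")
  p
}

#' Extract one coordinate of one keypoint as a scalar series
#' @inheritParams keypoint_xyz
#' @param axis one of `"x"`, `"y"`, `"z"`.
#' @return a [scalar_series()] in meters.
#' @export
keypoint_series <- function(traj, name, axis = "x") {
  axis <- match.arg(axis, c("x", "y", "z"))
  xyz <- keypoint_xyz(traj, name)
  scalar_series(xyz[, axis], traj$sample_rate, traj$t0, "m")
}

# required keypoints per input dialect
.dialect_required <- list(
  markerless = c("left_heel", "right_heel", "left_ear", "right_ear", "nose"),
  markered   = c("left_foot", "right_foot", "head")
)

#' Read a keypoint trajectory from the canonical CSV
#'
#' The canonical CSV has one metadata comment line
#' (`# sample_rate_hz=<r> frame=<tag> t0=<s>`), a header
#' `time_s,<name>_x,<name>_y,<name>_z,...`, and numeric rows in meters.
#' Timestamps must be uniform to within 1e-4 s. Isolated missing samples
#' (gaps of at most `max_gap` consecutive samples per coordinate) are
#' linearly interpolated; longer gaps raise a data-quality error naming the
#' keypoint and interval.
#'
#' @param path file to read.
#' @param dialect `"markerless"` (requires left_heel, right_heel, left_ear,
#'   right_ear, nose) or `"markered"` (requires left_foot, right_foot, head).
#' @param sample_rate expected rate in Hz; if `NULL`, taken from the metadata
#'   line (or inferred from timestamps when no metadata line is present).
#' @param max_gap longest run of missing samples to interpolate (default 5).
#' @return a [kpt_traj()].
#' @export
read_keypoints <- function(path, dialect = c("markerless", "markered"),
                           sample_rate = NULL, max_gap = 5) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1)
  meta <- list()
  if (startsWith(first, "#")) {
    for (kv in strsplit(trimws(sub("^#", "", first)), "[, ]+")[[1]]) {
      p <- strsplit(kv, "=", fixed = TRUE)[[1]]
      if (length(p) == 2) meta[[p[1]]] <- p[2]
    }
  }
  dat <- utils::read.csv(path, comment.char = "#", check.names = FALSE)
  if (!"time_s" %in% names(dat)) stop("canonical keypoint CSV needs a 'time_s' column")

  cols <- setdiff(names(dat), "time_s")
  kp <- unique(sub("_[xyz]$", "", cols))
  missing_cols <- setdiff(c(paste0(rep(kp, each = 3), "_", c("x", "y", "z"))), cols)
  if (length(missing_cols)) stop("incomplete coordinate triplets: ",
                                 paste(missing_cols, collapse = ", "))
  req <- .dialect_required[[dialect]]
  absent <- setdiff(req, kp)
  if (length(absent))
    stop("missing required keypoint(s) for dialect '", dialect, "': ",
         paste(absent, collapse = ", "))

  n <- nrow(dat)
  if (!is.null(meta$sample_rate_hz)) {
    fs_meta <- as.numeric(meta$sample_rate_hz)
    if (is.null(sample_rate)) sample_rate <- fs_meta
  }
  t0 <- if (!is.null(meta$t0)) as.numeric(meta$t0) else if (n) dat$time_s[1] else 0
  if (is.null(sample_rate)) {
    if (n < 2) stop("sample_rate not given and cannot be inferred from ", n, " row(s)")
    sample_rate <- 1 / stats::median(diff(dat$time_s))
  }
  if (n >= 2) {
    expected <- t0 + (seq_len(n) - 1) / sample_rate
    if (max(abs(dat$time_s - expected)) > 1e-4)
      stop("non-uniform timestamps (tolerance 1e-4 s) for sample_rate = ", sample_rate, " Hz")
  }

  pos <- array(NA_real_, dim = c(n, length(kp), 3),
               dimnames = list(NULL, kp, c("x", "y", "z")))
  for (k in kp) for (ax in c("x", "y", "z")) {
    v <- dat[[paste0(k, "_", ax)]]
    if (anyNA(v)) {
      if (n >= 2) {
        runs <- rle(is.na(v))
        ends <- cumsum(runs$lengths)
        starts <- ends - runs$lengths + 1
        bad <- which(runs$values & runs$lengths > max_gap)
        if (length(bad))
          stop(sprintf("gap of %d samples (> max_gap = %d) in %s_%s over [%g s, %g s]",
                       runs$lengths[bad[1]], max_gap, k, ax,
                       dat$time_s[starts[bad[1]]], dat$time_s[ends[bad[1]]]))
      }
      v <- zoo::na.approx(v, x = dat$time_s, na.rm = FALSE, rule = 2)
      if (anyNA(v)) stop("could not interpolate all gaps in ", k, "_", ax)
    }
    pos[, k, ax] <- v
  }
  frame <- if (!is.null(meta$frame)) meta$frame else "raw"
  kpt_traj(pos, sample_rate, t0, frame_tag = frame)
}

#' Write a keypoint trajectory to the canonical CSV
#'
#' Positions are written at full double precision so that
#' `read_keypoints(write_keypoints(t))` round-trips to better than 1e-9 m.
#'
#' @param traj a [kpt_traj()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_keypoints <- function(traj, path) {
  stopifnot(inherits(traj, "kpt_traj"))
  kp <- keypoint_names(traj)
  n <- n_samples(traj)
  df <- data.frame(time_s = traj_time(traj))
  for (k in kp) for (ax in c("x", "y", "z"))
    df[[paste0(k, "_", ax)]] <- traj$positions[, k, ax]
  if (!n) { # header-only degenerate file
    df <- df[0, c("time_s", paste0(rep(kp, each = 3), "_", c("x", "y", "z"))), drop = FALSE]
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# sample_rate_hz=%.10g frame=%s t0=%.10g",
                     traj$sample_rate, traj$frame_tag, traj$t0), con)
  utils::write.csv(format(df, digits = 17, scientific = FALSE, trim = TRUE),
                   con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a simulator ground-truth JSON sidecar
#' @param path JSON file written by [write_ground_truth()].
#' @return the `gait_truth` object.
#' @export
read_ground_truth <- function(path) {
  g <- jsonlite::read_json(path, simplifyVector = TRUE)
  g$footsteps <- as.data.frame(g$footsteps)
  class(g) <- "gait_truth"
  g
}

#' Write a simulator ground-truth JSON sidecar
#' @param truth a `gait_truth` object (see [simulate_walk()]).
#' @param path output JSON file.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", pretty = TRUE)
  invisible(path)
}
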