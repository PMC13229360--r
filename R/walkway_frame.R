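#' Walkway coordinate frame
#'
#' Rigid rotation + translation + per-axis multiplicative scale mapping raw
#' capture coordinates into walkway coordinates (x forward, y toward the
#' subject's left, z up): `p_walkway = diag(axis_scale) %*% R %*% (p - origin)`.
#'
#' The frame is fitted from three calibration stances on the physical
#' walkway: at the walkway origin, a known distance forward along it, and a
#' known distance to the right of it. Because those two distances are known,
#' each horizontal axis receives a multiplicative bias correction
#' (`axis_scale`); the vertical scale defaults to the mean of the two
#' horizontal scales.
#'
#' @param p_origin,p_forward,p_right 3-vectors: measured positions of the
#'   three calibration stances in raw coordinates (e.g. the median position
#'   over each standing window).
#' @param forward_dist true forward distance in meters (default 5.0).
#' @param right_dist true rightward distance in meters (default 1.0).
#' @return Object of class `walkway_frame` with fields `origin` (3-vector),
#'   `rotation` (3x3 orthonormal, raw -> walkway) and `axis_scale` (3-vector).
#' @export
fit_walkway_frame <- function(p_origin, p_forward, p_right,
                              forward_dist = 5.0, right_dist = 1.0) {
  p_origin <- as.numeric(p_origin); p_forward <- as.numeric(p_forward)
  p_right <- as.numeric(p_right)
  stopifnot(length(p_origin) == 3, length(p_forward) == 3, length(p_right) == 3)
  f <- p_forward - p_origin
  r <- p_right - p_origin
  nf <- sqrt(sum(f^2))
  if (nf < 1e-9) stop("degenerate frame: forward calibration point coincides with origin")
  e1 <- f / nf
  ml <- r - sum(r * e1) * e1
  nml <- sqrt(sum(ml^2))
  if (nml < 1e-9 * max(1, sqrt(sum(r^2))))
    stop("degenerate frame: calibration points are collinear")
  e2 <- -ml / nml                     # p_right lies to the right -> y is +left
  e3 <- c(e1[2] * e2[3] - e1[3] * e2[2],
          e1[3] * e2[1] - e1[1] * e2[3],
          e1[1] * e2[2] - e1[2] * e2[1])
  R <- rbind(e1, e2, e3)
  dimnames(R) <- NULL
  s1 <- forward_dist / nf
  s2 <- right_dist / nml
  scale <- c(s1, s2, (s1 + s2) / 2)
  if (any(scale < 0.8 | scale > 1.2))
    warning(sprintf("axis_scale outside the [0.8, 1.2] sanity band: [%s]",
                    paste(sprintf("%.4f", scale), collapse = ", ")))
  structure(list(origin = p_origin, rotation = R, axis_scale = scale),
            class = "walkway_frame")
}

#' @export
print.walkway_frame <- function(x, ...) {
  cat("<walkway_frame>\n  origin:", sprintf("%.4f", x$origin), "\n")
  cat("  axis_scale:", sprintf("%.4f", x$axis_scale), "\n")
  invisible(x)
}

# internal: map an n x 3 matrix of raw points into walkway coordinates
frame_map <- function(frame, p) {
  p <- sweep(p, 2, frame$origin)
  sweep(p %*% t(frame$rotation), 2, frame$axis_scale, `*`)
}

# internal: inverse map (walkway -> raw)
frame_unmap <- function(frame, p) {
  p <- sweep(p, 2, frame$axis_scale, `/`)
  sweep(p %*% frame$rotation, 2, frame$origin, `+`)
}

#' Apply (or invert) a walkway frame on a trajectory
#'
#' Every position `p` becomes `diag(axis_scale) R (p - origin)` and the
#' trajectory is retagged `frame_tag = "walkway"`. Applying a frame to data
#' already in walkway coordinates is an error; `invert_frame()` maps walkway
#' data back to raw coordinates.
#'
#' @param traj a [kpt_traj()] with `frame_tag = "raw"`.
#' @param frame a [fit_walkway_frame()] result.
#' @return The transformed `kpt_traj`.
#' @export
apply_frame <- function(traj, frame) {
  stopifnot(inherits(traj, "kpt_traj"), inherits(frame, "walkway_frame"))
  if (traj$frame_tag != "raw")
    stop("trajectory is already in walkway coordinates; refusing to re-apply the frame")
  out <- traj
  for (k in keypoint_names(traj)) {
    p <- traj$positions[, k, , drop = FALSE]
    dim(p) <- c(dim(p)[1], 3)
    out$positions[, k, ] <- frame_map(frame, p)
  }
  out$frame_tag <- "walkway"
  out
}

#' @rdname apply_frame
#' @export
invert_frame <- function(traj, frame) {
  stopifnot(inherits(traj, "kpt_traj"), inherits(frame, "walkway_frame"))
  if (traj$frame_tag != "walkway")
    stop("invert_frame expects a walkway-frame trajectory")
  out <- traj
  for (k in keypoint_names(traj)) {
    p <- traj$positions[, k, , drop = FALSE]
    dim(p) <- c(dim(p)[1], 3)
    out$positions[, k, ] <- frame_unmap(frame, p)
  }
  out$frame_tag <- "raw"
  out
}

#' Store / load a walkway frame as JSON
#' @param frame a `walkway_frame`.
#' @param path JSON file.
#' @return `read_frame()` returns the `walkway_frame`; `write_frame()` the
#'   path, invisibly.
#' @export
write_frame <- function(frame, path) {
  jsonlite::write_json(
    list(origin = frame$origin,
         rotation_row_major = as.numeric(t(frame$rotation)),
         axis_scale = frame$axis_scale),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_frame
#' @export
read_frame <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(origin = j$origin,
                 rotation = matrix(j$rotation_row_major, 3, 3, byrow = TRUE),
                 axis_scale = j$axis_scale),
            class = "walkway_frame")
}
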