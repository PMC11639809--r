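#' Tracker configuration
#'
#' Defaults follow the reference operating point: up to 200 feature points,
#' FAST contrast threshold 2 gray levels, one point per 4 x 4 pixel grid
#' cell. The Lucas-Kanade settings (21 x 21 window, 3 pyramid levels, 30
#' iterations, epsilon 0.01) are the common pyramidal-LK operating point.
#'
#' @param max_points maximum number of feature points (N).
#' @param contrast_threshold FAST segment-test threshold, gray levels.
#' @param cell_size spatial bucketing grid cell size, pixels.
#' @param lk_window side length of the LK integration window, pixels (odd).
#' @param lk_levels pyramid levels.
#' @param lk_max_iter,lk_eps iteration cap and convergence threshold.
#' @return An object of class `tracker_config`.
#' @export
tracker_config <- function(max_points = 200L, contrast_threshold = 2,
                           cell_size = 4L, lk_window = 21L, lk_levels = 3L,
                           lk_max_iter = 30L, lk_eps = 0.01) {
  if (max_points < 1L || contrast_threshold < 1 || cell_size < 1L) {
    stop_input("max_points, contrast_threshold and cell_size must be >= 1",
               "ovirr_parameter_error")
  }
  structure(list(max_points = as.integer(max_points),
                 contrast_threshold = contrast_threshold,
                 cell_size = as.integer(cell_size),
                 lk_window = as.integer(lk_window),
                 lk_levels = as.integer(lk_levels),
                 lk_max_iter = as.integer(lk_max_iter), lk_eps = lk_eps),
            class = "tracker_config")
}

#' Detect trackable feature points inside a mask
#'
#' FAST-style segment test on a Bresenham circle of 16 pixels (arc length 9):
#' a pixel is a feature point when a contiguous arc of at least nine circle
#' pixels is uniformly brighter or darker than the center by more than the
#' contrast threshold. Detections are restricted to the mask, spatially
#' spread by keeping at most one point (the strongest) per `cell_size` grid
#' cell, ordered by corner score descending, and capped at `max_points`.
#'
#' @param image enhanced grayscale matrix (the masked, CLAHE-equalised first
#'   frame).
#' @param mask binary matrix or [instance_mask]; `NULL` means the whole image.
#' @param cfg a [tracker_config].
#' @return A data frame with columns `x`, `y` (1-based pixel coordinates)
#'   and `score`; zero rows when no contrast is found.
#' @export
detect_feature_points <- function(image, mask = NULL, cfg = tracker_config()) {
  pts <- .fast_detect_cpp(image, cfg$contrast_threshold)
  if (!is.null(mask)) {
    if (inherits(mask, "instance_mask")) mask <- mask$mask
    keep <- mask[cbind(pts$y, pts$x)] != 0
    pts <- pts[keep, , drop = FALSE]
  }
  if (nrow(pts) == 0L) {
    message("detect_feature_points: no feature point found")
    return(pts)
  }
  cell <- (pts$x - 1L) %/% cfg$cell_size +
    ((pts$y - 1L) %/% cfg$cell_size) * 1e6
  # strongest point per cell; ties resolved by scan order (deterministic)
  ord <- order(cell, -pts$score, pts$y, pts$x)
  pts <- pts[ord, , drop = FALSE]
  pts <- pts[!duplicated(cell[ord]), , drop = FALSE]
  pts <- pts[order(-pts$score, pts$y, pts$x), , drop = FALSE]
  head(pts, cfg$max_points)
}

#' Track feature points with pyramidal Lucas-Kanade optical flow
#'
#' Positions are chained frame to frame: the flow from frame t to t+1 is
#' solved with an iterative pyramidal Lucas-Kanade step seeded at the
#' previous position. A point whose solve fails (singular normal matrix at
#' the base level) or that exits the image is marked invalid from that frame
#' on; points are seeded once and never re-detected.
#'
#' @param frames a [frame_sequence] (RGB frames are converted to luminance)
#'   or a list of grayscale matrices.
#' @param seeds data frame or matrix of seed positions (`x`, `y`).
#' @param cfg a [tracker_config].
#' @return An object of class `trajectory_set` with fields `positions`
#'   (N x T x 2 array of x then y), `valid` (N x T logical, monotone
#'   non-increasing over time), and `fps`.
#' @export
track <- function(frames, seeds, cfg = tracker_config()) {
  fps <- if (inherits(frames, "frame_sequence")) frames$fps else NA_real_
  mats <- if (inherits(frames, "frame_sequence")) as_gray(frames) else frames
  if (length(mats) < 2L) stop_input("need at least 2 frames", "ovirr_parameter_error")
  if (is.data.frame(seeds)) seeds <- cbind(seeds$x, seeds$y)
  if (is.null(dim(seeds)) || nrow(seeds) == 0L) {
    stop_input("seeds must be a nonempty set of (x, y) points",
               "ovirr_parameter_error")
  }
  res <- .lk_track_cpp(mats, as.matrix(seeds),
                       half_win = (cfg$lk_window - 1L) %/% 2L,
                       levels = cfg$lk_levels, max_iter = cfg$lk_max_iter,
                       eps = cfg$lk_eps)
  structure(list(positions = res$positions, valid = res$valid, fps = fps),
            class = "trajectory_set")
}

#' @export
print.trajectory_set <- function(x, ...) {
  n <- dim(x$positions)[1]; t <- dim(x$positions)[2]
  cat(sprintf("<trajectory_set> %d points x %d frames, %d fully valid\n",
              n, t, sum(rowSums(x$valid) == t)))
  invisible(x)
}

#' Differentiate trajectories into motion signals
#'
#' Applies the first-order discrete difference along time to the horizontal
#' and vertical coordinates of every fully valid trajectory. Differencing
#' removes the (rotation-sensitive) absolute position and leaves the
#' frame-to-frame displacement that encodes chest expansion; the derivative
#' is a plain first difference, without frame-rate scaling, since the
#' spectral analysis downstream is amplitude-scale invariant.
#'
#' @param traj a [trajectory_set].
#' @return An object of class `motion_signals` with `dx`, `dy`
#'   (M x (T-1) matrices, M = number of fully valid trajectories) and `fps`.
#' @export
differentiate <- function(traj) {
  stopifnot(inherits(traj, "trajectory_set"))
  t_len <- dim(traj$positions)[2]
  full <- rowSums(traj$valid) == t_len
  if (!any(full)) {
    stop_input("no trajectory remained valid over all frames",
               "ovirr_degenerate_input")
  }
  px <- traj$positions[full, , 1, drop = FALSE][, , 1]
  py <- traj$positions[full, , 2, drop = FALSE][, , 1]
  if (is.null(dim(px))) { px <- matrix(px, 1); py <- matrix(py, 1) }
  dx <- px[, -1, drop = FALSE] - px[, -t_len, drop = FALSE]
  dy <- py[, -1, drop = FALSE] - py[, -t_len, drop = FALSE]
  structure(list(dx = dx, dy = dy, fps = traj$fps), class = "motion_signals")
}
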