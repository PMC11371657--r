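# Per-track kinematics: speed, net-to-gross displacement ratio, smoothed
# orientation and angular velocity, motility classification, reversal
# detection and per-interval reversal rates.

#' Frame-to-frame speed series
#'
#' Centroid displacement per inter-frame interval divided by the interval
#' duration.
#'
#' @param traj data.frame for one cell with `t_min`, `x_um`, `y_um`,
#'   ordered by time.
#' @return numeric vector of length `nrow(traj) - 1` (um/min).
#' @export
compute_speed <- function(traj) {
  stopifnot(nrow(traj) >= 2)
  dt <- diff(traj$t_min)
  if (any(dt <= 0)) stop("timestamps must be strictly increasing")
  sqrt(diff(traj$x_um)^2 + diff(traj$y_um)^2) / dt
}

#' Net-to-gross displacement ratio
#'
#' `NGDR = |end - start| / sum(|step|)`: 1 for straight monotone paths,
#' approaching 0 for cells jostling in place. Defined as 0 when the gross
#' displacement is zero.
#'
#' @param traj trajectory data.frame (`x_um`, `y_um`).
#' @return scalar in \[0, 1\].
#' @export
compute_ngdr <- function(traj) {
  stopifnot(nrow(traj) >= 2)
  gross <- sum(sqrt(diff(traj$x_um)^2 + diff(traj$y_um)^2))
  if (gross == 0) return(0)
  net <- sqrt((traj$x_um[nrow(traj)] - traj$x_um[1])^2 +
              (traj$y_um[nrow(traj)] - traj$y_um[1])^2)
  net / gross
}

#' Savitzky-Golay smoothed orientation series
#'
#' Unwraps the axial (mod-pi) orientation to a continuous signal and applies
#' a first-order Savitzky-Golay filter over a centred window of the stated
#' duration: each output sample is the local linear least-squares fit
#' evaluated at the window centre, so constant and linear series pass
#' through unchanged.
#'
#' @param orientation axial angles (radians), one per frame.
#' @param t_min frame times (min), uniformly spaced.
#' @param window window duration (min).
#' @param order polynomial order.
#' @return numeric vector of smoothed (unwrapped) angles.
#' @export
smooth_orientation <- function(orientation, t_min, window = 20, order = 1) {
  n <- length(orientation)
  stopifnot(length(t_min) == n)
  unwrapped <- unwrap_axial(orientation)
  if (n < 3) return(unwrapped)
  dt <- stats::median(diff(t_min))
  n_win <- round(window / dt)
  if (n_win %% 2 == 0) n_win <- n_win + 1
  if (n_win > n) {
    warning("smoothing window longer than the series; returning unsmoothed")
    return(unwrapped)
  }
  if (n_win < order + 2) return(unwrapped)
  signal::sgolayfilt(unwrapped, p = order, n = n_win)
}

#' Angular velocity from a smoothed orientation series
#'
#' Central differences of the smoothed series (one-sided at the ends).
#'
#' @param smoothed smoothed orientation (radians).
#' @param t_min frame times (min).
#' @return rad/min, same length as the input.
#' @export
angular_velocity <- function(smoothed, t_min) {
  n <- length(smoothed)
  if (n < 2) return(rep(0, n))
  omega <- numeric(n)
  omega[1] <- (smoothed[2] - smoothed[1]) / (t_min[2] - t_min[1])
  omega[n] <- (smoothed[n] - smoothed[n - 1]) / (t_min[n] - t_min[n - 1])
  if (n > 2) {
    omega[2:(n - 1)] <- (smoothed[3:n] - smoothed[1:(n - 2)]) /
      (t_min[3:n] - t_min[1:(n - 2)])
  }
  omega
}

#' Classify a trajectory's motility
#'
#' Rule order: mean speed below `v_stationary` gives `"stationary"`;
#' otherwise the cell is candidate motile, demoted to
#' `"excluded_jostling"` if its NGDR is below `ngdr_min` (jostling in place)
#' or to `"excluded_rotating"` if its smoothed angular velocity magnitude
#' exceeds `omega_max` for a contiguous period longer than `omega_duration`;
#' everything else is `"motile"`. Single-frame tracks are classed
#' stationary.
#'
#' @param traj trajectory data.frame (`t_min`, `x_um`, `y_um`,
#'   `orientation_rad`).
#' @param v_stationary stationary speed threshold (um/min).
#' @param ngdr_min minimum NGDR for motile cells.
#' @param omega_max angular-velocity threshold (rad/min).
#' @param omega_duration contiguous duration above `omega_max` that triggers
#'   exclusion (min).
#' @param sg_window Savitzky-Golay window for the orientation series (min).
#' @return character scalar motility class.
#' @export
classify_motility <- function(traj, v_stationary = 0.038, ngdr_min = 0.04,
                              omega_max = 0.073, omega_duration = 2,
                              sg_window = 20) {
  if (nrow(traj) < 2) return("stationary")
  mean_speed <- mean(compute_speed(traj))
  if (mean_speed < v_stationary) return("stationary")
  if (compute_ngdr(traj) < ngdr_min) return("excluded_jostling")
  sm <- suppressWarnings(
    smooth_orientation(traj$orientation_rad, traj$t_min, window = sg_window))
  omega <- angular_velocity(sm, traj$t_min)
  above <- abs(omega) > omega_max
  if (any(above)) {
    r <- rle(above)
    dt <- stats::median(diff(traj$t_min))
    if (any(r$lengths[r$values] * dt > omega_duration)) {
      return("excluded_rotating")
    }
  }
  "motile"
}

#' Detect reversals in a motile trajectory
#'
#' A reversal is logged at frame `k` when the dominant displacement
#' direction over the preceding `persistence` steps and the following
#' `persistence` steps differ by more than `angle_threshold`. Consecutive
#' detections within `persistence` frames merge into one event (the first
#' frame is kept). Windows with negligible net movement are skipped.
#'
#' @param traj trajectory data.frame.
#' @param angle_threshold direction change that counts as a reversal
#'   (radians; default 150 degrees).
#' @param persistence window half-width in frames.
#' @param min_disp minimum net window displacement (um) for a defined
#'   direction.
#' @return integer vector of reversal frame indices (0-based, relative to
#'   `traj$frame` if present, else row position - 1).
#' @export
detect_reversals <- function(traj, angle_threshold = 150 * pi / 180,
                             persistence = 2, min_disp = 1e-6) {
  n <- nrow(traj)
  frames <- if ("frame" %in% names(traj)) traj$frame else seq_len(n) - 1L
  if (n < 2 * persistence + 1) return(integer())
  dx <- diff(traj$x_um); dy <- diff(traj$y_um)
  hits <- integer()
  for (k in (persistence + 1):(n - persistence)) {
    before <- c(sum(dx[(k - persistence):(k - 1)]),
                sum(dy[(k - persistence):(k - 1)]))
    after <- c(sum(dx[k:(k + persistence - 1)]),
               sum(dy[k:(k + persistence - 1)]))
    nb <- sqrt(sum(before^2)); na <- sqrt(sum(after^2))
    if (nb < min_disp || na < min_disp) next
    cosang <- sum(before * after) / (nb * na)
    ang <- acos(pmin(pmax(cosang, -1), 1))
    if (ang > angle_threshold) hits <- c(hits, k)
  }
  if (length(hits) == 0) return(integer())
  keep <- c(TRUE, diff(hits) > persistence)
  frames[hits[keep]]
}

#' Leading-pole label per frame
#'
#' The pole endpoint (centroid +/- (length/2) * axis) with the larger
#' positive projection on the instantaneous velocity is the leading pole:
#' label 1 for the +axis endpoint, 2 for the -axis endpoint, `NA` where the
#' instantaneous speed is below `v_stationary` (undefined direction).
#' Velocity is taken as the central difference of the centroid.
#'
#' @param traj trajectory data.frame (`t_min`, `x_um`, `y_um`,
#'   `orientation_rad`).
#' @param v_stationary speed below which the label is undefined (um/min).
#' @return integer vector (1, 2 or NA) per frame.
#' @export
leading_pole_assignment <- function(traj, v_stationary = 0.038) {
  n <- nrow(traj)
  if (n < 2) return(rep(NA_integer_, n))
  vx <- angular_velocity(traj$x_um, traj$t_min)  # central differences
  vy <- angular_velocity(traj$y_um, traj$t_min)
  speed <- sqrt(vx^2 + vy^2)
  proj <- cos(traj$orientation_rad) * vx + sin(traj$orientation_rad) * vy
  out <- ifelse(proj > 0, 1L, 2L)
  out[proj == 0 | speed < v_stationary] <- NA_integer_
  out
}

#' Per-interval reversal counts and rates
#'
#' Counts reversal events (`n_r`) and trajectory points (`n_t`) in each
#' half-open time interval `[boundaries[i], boundaries[i+1])` and reports
#' the per-point rate `n_r / n_t` (convertible to per-minute rates via the
#' frame rate).
#'
#' @param points data.frame of trajectory points with `t_min` and a logical
#'   `is_reversal` column.
#' @param boundaries increasing numeric vector of interval boundaries
#'   (length = number of intervals + 1).
#' @param labels optional interval labels (default `t1`, `t2`, ...).
#' @return data.frame: `interval`, `n_r`, `n_t`, `rate` (NA for empty
#'   intervals).
#' @export
reversal_rate_series <- function(points, boundaries, labels = NULL) {
  stopifnot(all(c("t_min", "is_reversal") %in% names(points)),
            !is.unsorted(boundaries, strictly = TRUE))
  k <- length(boundaries) - 1
  if (is.null(labels)) labels <- paste0("t", seq_len(k))
  idx <- findInterval(points$t_min, boundaries,
                      rightmost.closed = FALSE, left.open = FALSE)
  n_t <- tabulate(idx[idx >= 1 & idx <= k], nbins = k)
  n_r <- tabulate(idx[points$is_reversal & idx >= 1 & idx <= k], nbins = k)
  data.frame(interval = labels, n_r = n_r, n_t = n_t,
             rate = ifelse(n_t > 0, n_r / n_t, NA_real_))
}

#' Annotate a trajectory table with kinematics
#'
#' Convenience wrapper applying [compute_speed()], [compute_ngdr()],
#' [smooth_orientation()]/[angular_velocity()], [classify_motility()] and
#' [detect_reversals()] per cell to a multi-cell trajectory table.
#'
#' @param poses trajectory table with `cell_id`, `frame`, `t_min`, `x_um`,
#'   `y_um`, `orientation_rad`.
#' @param ... passed to [classify_motility()].
#' @return the table with `speed_um_min`, `ngdr`, `omega_rad_min`,
#'   `motility_class`, `is_reversal` columns appended.
#' @export
annotate_kinematics <- function(poses, ...) {
  stopifnot(all(c("cell_id", "t_min", "x_um", "y_um") %in% names(poses)))
  parts <- split(poses, poses$cell_id)
  parts <- lapply(parts, function(tr) {
    tr <- tr[order(tr$t_min), ]
    n <- nrow(tr)
    if (n < 2) {
      tr$speed_um_min <- NA_real_
      tr$ngdr <- NA_real_
      tr$omega_rad_min <- NA_real_
      tr$motility_class <- "stationary"
      tr$is_reversal <- FALSE
      return(tr)
    }
    sp <- compute_speed(tr)
    tr$speed_um_min <- c(sp[1], sp)       # per-frame, backward difference
    tr$ngdr <- compute_ngdr(tr)
    sm <- suppressWarnings(
      smooth_orientation(tr$orientation_rad, tr$t_min))
    tr$omega_rad_min <- angular_velocity(sm, tr$t_min)
    tr$motility_class <- classify_motility(tr, ...)
    rev_frames <- if (tr$motility_class[1] == "motile") {
      detect_reversals(tr)
    } else integer()
    tr$is_reversal <- tr$frame %in% rev_frames
    tr
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}
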