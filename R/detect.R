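# Cell detection and track linking on cell-channel frames.
#
# Stands in for the interactive trackers used on real data: threshold ->
# connected components -> per-component pose from image moments, then
# greedy nearest-neighbour linking. Adequate for the sparse synthetic
# monolayers this package generates; dense-cluster splitting and lineage
# tracking are out of scope.

#' Segment one cell-channel frame
#'
#' Thresholds the image, labels connected components, and estimates a pose
#' per component: centroid, principal-axis orientation (from second
#' moments), and length/width as the component's extent along / across the
#' principal axis. When a fluorescence image is supplied, the mean
#' fluorescence under each component mask is recorded (used by
#' [filter_cells()] to reject detritus lacking reporter signal).
#'
#' @param image 2-D numeric matrix (cell channel).
#' @param intensity_threshold scalar; pixels above it are foreground.
#'   Default: midway between the image minimum and maximum.
#' @param pixel_size um per pixel.
#' @param fluor_image optional matrix of the same size.
#' @param min_area_px components smaller than this are discarded as noise.
#' @return data.frame with one row per detected cell: `x_um`, `y_um`,
#'   `length_um`, `width_um`, `orientation_rad` (axial, in `[0, pi)`),
#'   `aspect_ratio`, `area_px`, `mean_fluor`.
#' @export
segment_frame <- function(image, intensity_threshold = NULL, pixel_size = 0.1,
                          fluor_image = NULL, min_area_px = 10) {
  stopifnot(is.matrix(image))
  empty <- data.frame(x_um = numeric(), y_um = numeric(),
                      length_um = numeric(), width_um = numeric(),
                      orientation_rad = numeric(), aspect_ratio = numeric(),
                      area_px = integer(), mean_fluor = numeric())
  if (length(image) == 0) return(empty)
  if (is.null(intensity_threshold)) {
    intensity_threshold <- (min(image) + max(image)) / 2
  }
  mask <- image > intensity_threshold
  if (!any(mask)) return(empty)
  lab <- EBImage::bwlabel(mask)
  lab <- as.matrix(lab)
  idx <- which(lab > 0)
  comp <- lab[idx]
  rows <- (idx - 1) %% nrow(lab) + 1
  cols <- (idx - 1) %/% nrow(lab) + 1
  out <- lapply(sort(unique(comp)), function(cc) {
    sel <- comp == cc
    if (sum(sel) < min_area_px) return(NULL)
    # pixel-centre coordinates in um
    x <- (cols[sel] - 0.5) * pixel_size
    y <- (rows[sel] - 0.5) * pixel_size
    cx <- mean(x); cy <- mean(y)
    cov <- stats::cov(cbind(x, y)) * (length(x) - 1) / length(x)
    eg <- eigen(cov, symmetric = TRUE)
    v <- eg$vectors[, 1]
    theta <- wrap_axial(atan2(v[2], v[1]))
    u <- c(cos(theta), sin(theta))
    along <- (x - cx) * u[1] + (y - cy) * u[2]
    across <- -(x - cx) * u[2] + (y - cy) * u[1]
    len <- diff(range(along)) + pixel_size
    wid <- diff(range(across)) + pixel_size
    mf <- if (is.null(fluor_image)) NA_real_ else {
      mean(fluor_image[idx[sel]])
    }
    data.frame(x_um = cx, y_um = cy, length_um = len, width_um = wid,
               orientation_rad = theta, aspect_ratio = len / wid,
               area_px = sum(sel), mean_fluor = mf)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) empty else out
}

#' Link per-frame detections into trajectories
#'
#' Greedy nearest-neighbour assignment between consecutive frames with no
#' gap tolerance: candidate links are taken in order of increasing centroid
#' distance, links longer than `max_step` are rejected, and unmatched
#' detections start new tracks. Tracks of cells that leave the field simply
#' terminate at their last visible frame.
#'
#' @param frames list of data.frames from [segment_frame()], one per
#'   consecutive frame (frame index = position in the list - 1).
#' @param max_step maximum link distance (um per frame).
#' @param frame_rate frames/min, used to populate the time column.
#' @return single data.frame of poses with `cell_id`, `frame` and `t_min`
#'   prepended, ordered by cell then frame.
#' @export
link_tracks <- function(frames, max_step = 2, frame_rate = 7.5) {
  stopifnot(is.list(frames))
  next_id <- 1L
  linked <- vector("list", length(frames))
  prev_ids <- integer()
  for (f in seq_along(frames)) {
    det <- frames[[f]]
    n <- nrow(det)
    ids <- integer(n)
    if (n > 0 && length(prev_ids) > 0) {
      prev <- linked[[f - 1]]
      d <- outer(seq_len(nrow(prev)), seq_len(n), function(i, j) {
        sqrt((prev$x_um[i] - det$x_um[j])^2 + (prev$y_um[i] - det$y_um[j])^2)
      })
      repeat {
        m <- which.min(d)
        if (length(m) == 0 || d[m] > max_step || !is.finite(d[m])) break
        i <- (m - 1) %% nrow(d) + 1
        j <- (m - 1) %/% nrow(d) + 1
        ids[j] <- prev$cell_id[i]
        d[i, ] <- Inf
        d[, j] <- Inf
      }
    }
    if (n > 0) {
      new <- ids == 0L
      if (any(new)) {
        ids[new] <- seq.int(next_id, length.out = sum(new))
        next_id <- next_id + sum(new)
      }
      det$cell_id <- ids
      det$frame <- f - 1L
      det$t_min <- (f - 1L) / frame_rate
    }
    linked[[f]] <- det
    prev_ids <- ids
  }
  out <- do.call(rbind, linked[vapply(linked, nrow, 1L) > 0])
  if (is.null(out)) {
    return(cbind(data.frame(cell_id = integer(), frame = integer(),
                            t_min = numeric()), frames[[1]][0, ]))
  }
  out[order(out$cell_id, out$frame),
      c("cell_id", "frame", "t_min",
        setdiff(names(out), c("cell_id", "frame", "t_min")))]
}

#' Filter detections on reporter signal and aspect ratio
#'
#' Applies the object filters used before any polarity analysis: objects
#' without appreciable fluorescence signal (cell fragments and other
#' detritus) are rejected, as are cells with aspect ratio below
#' `min_aspect_ratio` (cells not attached to the surface by both poles).
#' The aspect-ratio boundary is inclusive: exactly 1.4 is kept.
#'
#' @param poses data.frame with `aspect_ratio` and `mean_fluor` columns.
#' @param min_mean_fluor minimum mean fluorescence (a.u.); see
#'   [suggest_fluor_threshold()].
#' @param min_aspect_ratio minimum aspect ratio (default 1.4).
#' @return list with `kept` (data.frame) and `rejected` (data.frame with a
#'   `reason` column, `"no_fluor"` or `"aspect_ratio"`).
#' @export
filter_cells <- function(poses, min_mean_fluor, min_aspect_ratio = 1.4) {
  stopifnot(all(c("aspect_ratio", "mean_fluor") %in% names(poses)))
  no_fluor <- !is.na(poses$mean_fluor) & poses$mean_fluor < min_mean_fluor
  low_ar <- poses$aspect_ratio < min_aspect_ratio
  reason <- ifelse(no_fluor, "no_fluor",
                   ifelse(low_ar, "aspect_ratio", NA_character_))
  keep <- is.na(reason)
  rejected <- poses[!keep, , drop = FALSE]
  if (nrow(rejected)) rejected$reason <- reason[!keep]
  else rejected$reason <- character()
  list(kept = poses[keep, , drop = FALSE], rejected = rejected)
}

#' Suggested fluorescence filter threshold
#'
#' Three times the image background median, the default working point for
#' [filter_cells()] (the threshold on real data is chosen by inspection).
#'
#' @param fluor_image fluorescence image matrix.
#' @return scalar threshold (a.u.).
#' @export
suggest_fluor_threshold <- function(fluor_image) {
  3 * stats::median(fluor_image)
}
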