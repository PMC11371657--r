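# Quantification of polar fluorescent-fusion localization along the cell.
#
# For each cell and fluorescence frame, the maximum intensity along 10
# parallel lines spanning the cell width gives a longitudinal profile that
# is robust to foci sitting slightly off the centreline and to small cell
# movement between channel acquisitions. Pole intensities are normalised by
# the mid-cell mean and thresholded into nonpolar / unipolar / bipolar
# classes, with a mid-cell exclusion for cells nearing division and a
# ratio-based reassignment of strongly asymmetric "bipolar" cells.

#' Polarity classification thresholds and profiler geometry
#'
#' @param I_min normalised pole intensity above which a pole counts as
#'   carrying a localization (strict inequality).
#' @param ratio_max pole-intensity ratio (larger/smaller) above which an
#'   initially bipolar cell is re-assigned unipolar at its stronger pole;
#'   must exceed 1.
#' @param n_lines number of parallel sampling lines.
#' @param line_spacing perpendicular spacing between lines (um); 10 lines at
#'   0.09 um span approximately one cell width (~0.9 um).
#' @param pole_fraction fraction of the cell length forming each pole
#'   window.
#' @param mid_fraction central fraction of the cell length over which the
#'   normalising mid-cell mean is taken.
#' @param midcell_tol relative margin by which the mid-cell mean must exceed
#'   both raw pole maxima before the mid-cell exclusion fires. Cells with a
#'   genuine nascent-pole localization exceed the pole signal many-fold; the
#'   margin only guards against near-ties on focus-free profiles, where the
#'   pole window of a short cell sits partly in the soft intensity falloff
#'   at the cell tip and its maximum runs a few percent below the
#'   body plateau.
#' @return object of class `threshold_config`.
#' @export
threshold_config <- function(I_min = 2, ratio_max = 3, n_lines = 10,
                             line_spacing = 0.09, pole_fraction = 0.1,
                             mid_fraction = 0.25, midcell_tol = 0.05) {
  check_finite(I_min = I_min, ratio_max = ratio_max)
  if (I_min <= 0) stop("I_min must be > 0")
  if (ratio_max <= 1) stop("ratio_max must be > 1")
  if (midcell_tol < 0) stop("midcell_tol must be >= 0")
  structure(list(I_min = I_min, ratio_max = ratio_max, n_lines = n_lines,
                 line_spacing = line_spacing, pole_fraction = pole_fraction,
                 mid_fraction = mid_fraction, midcell_tol = midcell_tol),
            class = "threshold_config")
}

## bilinear interpolation of image at (x, y) in um; NA outside
bilinear_sample <- function(image, x, y, pixel_size) {
  # pixel centres at (j - 0.5) * pixel_size
  gx <- x / pixel_size + 0.5
  gy <- y / pixel_size + 0.5
  j0 <- floor(gx); i0 <- floor(gy)
  fx <- gx - j0; fy <- gy - i0
  nr <- nrow(image); nc <- ncol(image)
  get <- function(i, j) {
    ok <- i >= 1 & i <= nr & j >= 1 & j <= nc
    v <- rep(NA_real_, length(i))
    v[ok] <- image[cbind(i[ok], j[ok])]
    v
  }
  v00 <- get(i0, j0); v01 <- get(i0, j0 + 1)
  v10 <- get(i0 + 1, j0); v11 <- get(i0 + 1, j0 + 1)
  out <- v00 * (1 - fx) * (1 - fy) + v01 * fx * (1 - fy) +
    v10 * (1 - fx) * fy + v11 * fx * fy
  out
}

#' Longitudinal maximum-intensity profile of a cell
#'
#' Lays `n_lines` parallel segments with the cell's orientation and length,
#' offset perpendicular to the body axis at `line_spacing`, samples the
#' fluorescence image by bilinear interpolation at fixed arclength
#' intervals (one pixel-equivalent), and takes the maximum across lines at
#' each arclength. Arclength 0 is pole 1 (the +axis endpoint), 1 is pole 2.
#'
#' @param image fluorescence image matrix.
#' @param pose one-row data.frame (`x_um`, `y_um`, `orientation_rad`,
#'   `length_um`).
#' @param cfg a [threshold_config()].
#' @param pixel_size um per pixel.
#' @return data.frame with `s` (normalised arclength) and `intensity`.
#' @export
sample_longitudinal_profile <- function(image, pose, cfg = threshold_config(),
                                        pixel_size = 0.1) {
  stopifnot(inherits(cfg, "threshold_config"))
  pp <- pole_positions(pose)
  perp <- c(-pp$u[2], pp$u[1])
  n_s <- max(5L, round(pose$length_um / pixel_size) + 1L)
  s <- seq(0, 1, length.out = n_s)
  base_x <- pp$p1[1] + s * (pp$p2[1] - pp$p1[1])
  base_y <- pp$p1[2] + s * (pp$p2[2] - pp$p1[2])
  offs <- (seq_len(cfg$n_lines) - (cfg$n_lines + 1) / 2) * cfg$line_spacing
  prof <- matrix(NA_real_, nrow = n_s, ncol = cfg$n_lines)
  for (li in seq_along(offs)) {
    prof[, li] <- bilinear_sample(image, base_x + offs[li] * perp[1],
                                  base_y + offs[li] * perp[2], pixel_size)
  }
  if (anyNA(prof)) {
    warning("pose partially outside the image; outside samples ignored")
  }
  intensity <- apply(prof, 1, function(r) {
    if (all(is.na(r))) NA_real_ else max(r, na.rm = TRUE)
  })
  data.frame(s = s, intensity = intensity)
}

#' Pole and mid-cell intensity metrics from a profile
#'
#' Raw pole maxima over the two pole windows (each `pole_fraction` of the
#' cell length), the mean over the central `mid_fraction`, and the
#' normalised pole intensities `I1 = pole1_max / mid_mean`,
#' `I2 = pole2_max / mid_mean`.
#'
#' @param profile data.frame from [sample_longitudinal_profile()].
#' @param cfg a [threshold_config()].
#' @return list: `pole1_max`, `pole2_max`, `mid_mean`, `I1`, `I2`, `valid`
#'   (FALSE with `reason` when the mid-cell mean is not positive).
#' @export
pole_metrics <- function(profile, cfg = threshold_config()) {
  s <- profile$s; v <- profile$intensity
  p1 <- max(v[s <= cfg$pole_fraction], na.rm = TRUE)
  p2 <- max(v[s >= 1 - cfg$pole_fraction], na.rm = TRUE)
  midlo <- 0.5 - cfg$mid_fraction / 2
  midhi <- 0.5 + cfg$mid_fraction / 2
  mid <- mean(v[s >= midlo & s <= midhi], na.rm = TRUE)
  if (!is.finite(mid) || mid <= 0) {
    return(list(pole1_max = p1, pole2_max = p2, mid_mean = mid,
                I1 = NA_real_, I2 = NA_real_, valid = FALSE,
                reason = "mid_mean_nonpositive"))
  }
  list(pole1_max = p1, pole2_max = p2, mid_mean = mid,
       I1 = p1 / mid, I2 = p2 / mid, valid = TRUE, reason = NA_character_)
}

#' Classify polarity from pole metrics
#'
#' Rule order: (1) mid-cell exclusion - if the raw mid-cell mean exceeds
#' both raw pole maxima the cell is nearing division and is
#' `"excluded_midcell"`; (2) thresholds - both `I > I_min` gives bipolar,
#' exactly one gives unipolar at that pole, neither gives nonpolar
#' (inequalities strict); (3) reassignment - a bipolar call with
#' `max(I1,I2)/min(I1,I2) > ratio_max` becomes unipolar at the stronger
#' pole.
#'
#' @param metrics list from [pole_metrics()].
#' @param cfg a [threshold_config()].
#' @return character class: `"nonpolar"`, `"unipolar_pole1"`,
#'   `"unipolar_pole2"`, `"bipolar"`, `"excluded_midcell"` or
#'   `"invalid"`.
#' @export
classify_polarity <- function(metrics, cfg = threshold_config()) {
  if (!isTRUE(metrics$valid)) return("invalid")
  tol <- cfg$midcell_tol %||% 0
  if (metrics$mid_mean > metrics$pole1_max * (1 + tol) &&
      metrics$mid_mean > metrics$pole2_max * (1 + tol)) {
    return("excluded_midcell")
  }
  a1 <- metrics$I1 > cfg$I_min
  a2 <- metrics$I2 > cfg$I_min
  if (a1 && a2) {
    ratio <- max(metrics$I1, metrics$I2) / min(metrics$I1, metrics$I2)
    if (ratio > cfg$ratio_max) {
      return(if (metrics$I1 >= metrics$I2) "unipolar_pole1" else "unipolar_pole2")
    }
    return("bipolar")
  }
  if (a1) return("unipolar_pole1")
  if (a2) return("unipolar_pole2")
  "nonpolar"
}

#' Build a polarity table for a set of cells and fluorescence frames
#'
#' @param images list of fluorescence image matrices, one per requested
#'   fluorescence frame.
#' @param poses data.frame of poses with `cell_id`, `fluor_frame` (matching
#'   positions in `images` via `fluor_frames`), `x_um`, `y_um`,
#'   `orientation_rad`, `length_um`, `t_min`.
#' @param fluor_frames integer frame indices corresponding to `images`.
#' @param cfg a [threshold_config()].
#' @param pixel_size um per pixel.
#' @return data.frame: `cell_id`, `fluor_frame`, `t_min`, `pole1_max`,
#'   `pole2_max`, `mid_mean`, `I1`, `I2`, `polarity_class`.
#' @export
polarity_table <- function(images, poses, fluor_frames,
                           cfg = threshold_config(), pixel_size = 0.1) {
  out <- vector("list", length(fluor_frames))
  for (k in seq_along(fluor_frames)) {
    ff <- fluor_frames[k]
    sub <- poses[poses$fluor_frame == ff, ]
    if (nrow(sub) == 0) next
    rows <- lapply(seq_len(nrow(sub)), function(i) {
      prof <- sample_longitudinal_profile(images[[k]], sub[i, ], cfg,
                                          pixel_size)
      m <- pole_metrics(prof, cfg)
      data.frame(cell_id = sub$cell_id[i], fluor_frame = ff,
                 t_min = sub$t_min[i], pole1_max = m$pole1_max,
                 pole2_max = m$pole2_max, mid_mean = m$mid_mean,
                 I1 = m$I1, I2 = m$I2,
                 polarity_class = classify_polarity(m, cfg),
                 stringsAsFactors = FALSE)
    })
    out[[k]] <- do.call(rbind, rows)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

## density anti-mode between the two dominant well-separated modes; NULL if
## effectively unimodal. The secondary mode must be at least min_sep (in
## units of the sample sd) from the primary and at least 5% of its height,
## which keeps jitter within one cluster from being mistaken for a mode.
find_antimode <- function(x, min_sep = 0.5) {
  if (length(unique(x)) < 5 || stats::sd(x) == 0) return(NULL)
  d <- stats::density(x, n = 512)
  y <- d$y
  ispeak <- which(diff(sign(diff(y))) == -2) + 1
  if (length(ispeak) < 2) return(NULL)
  main <- ispeak[which.max(y[ispeak])]
  sep <- min_sep * stats::sd(x)
  others <- ispeak[abs(d$x[ispeak] - d$x[main]) >= sep &
                     y[ispeak] >= 0.05 * y[main]]
  if (length(others) == 0) return(NULL)
  second <- others[which.max(y[others])]
  between <- seq(min(main, second), max(main, second))
  d$x[between[which.min(y[between])]]
}

#' Calibrate classification thresholds from a measured population
#'
#' Automated stand-in for choosing thresholds by visual inspection:
#' `I_min` is placed at the anti-mode of the pooled normalised pole
#' intensities (separating background poles from poles carrying a
#' localization), and `ratio_max` at the anti-mode of the per-cell
#' larger-to-smaller pole-intensity ratio distribution (separating
#' symmetric bipolar cells from strongly asymmetric unipolar ones). If a
#' distribution is unimodal the corresponding default is returned with a
#' warning.
#'
#' @param records data.frame with `I1` and `I2` columns (>= 100 rows).
#' @param defaults a [threshold_config()] supplying fallback values.
#' @return a [threshold_config()] with calibrated `I_min` and `ratio_max`,
#'   plus attribute `"pooled"` carrying the pooled intensities and ratios
#'   for operator review.
#' @export
calibrate_thresholds <- function(records, defaults = threshold_config()) {
  stopifnot(all(c("I1", "I2") %in% names(records)))
  ok <- is.finite(records$I1) & is.finite(records$I2)
  if (sum(ok) < 100) stop("need at least 100 complete (I1, I2) records")
  pooled <- c(records$I1[ok], records$I2[ok])
  ratios <- pmax(records$I1[ok], records$I2[ok]) /
    pmin(records$I1[ok], records$I2[ok])
  I_min <- find_antimode(pooled)
  if (is.null(I_min)) {
    warning("pooled pole-intensity distribution is unimodal; using default I_min")
    I_min <- defaults$I_min
  }
  log_ratio_split <- find_antimode(log(ratios))
  if (is.null(log_ratio_split) || exp(log_ratio_split) <= 1) {
    warning("pole-ratio distribution is unimodal; using default ratio_max")
    ratio_max <- defaults$ratio_max
  } else {
    ratio_max <- exp(log_ratio_split)
  }
  out <- threshold_config(I_min = I_min, ratio_max = ratio_max,
                          n_lines = defaults$n_lines,
                          line_spacing = defaults$line_spacing,
                          pole_fraction = defaults$pole_fraction,
                          mid_fraction = defaults$mid_fraction,
                          midcell_tol = defaults$midcell_tol %||% 0.05)
  attr(out, "pooled") <- list(pole_intensity = pooled, pole_ratio = ratios)
  out
}

#' Profile a simulated experiment's fluorescence frames
#'
#' Renders each fluorescence frame of a [simulate_experiment()] result on
#' demand, profiles every cell with the generator's pose table (poses come
#' from the coincident cell-channel frame, as on real data where tracking
#' is done in brightfield), and returns the polarity table. Images are
#' discarded after profiling, so memory stays flat for long runs.
#'
#' @param sim a `twitch_sim`.
#' @param cfg a [threshold_config()].
#' @param fluor_frames which fluorescence frames (default all).
#' @return polarity table as from [polarity_table()].
#' @export
profile_experiment <- function(sim, cfg = threshold_config(),
                               fluor_frames = NULL) {
  stopifnot(inherits(sim, "twitch_sim"))
  if (is.null(fluor_frames)) fluor_frames <- seq_along(sim$t_fluor) - 1L
  poses <- sim$ground_truth$poses
  out <- vector("list", length(fluor_frames))
  for (k in seq_along(fluor_frames)) {
    ff <- fluor_frames[k]
    cf <- ff * sim$fluor_stride
    img <- render_sim_frame(sim, cf, "fluor")$fluor
    sub <- poses[poses$frame == cf, ]
    sub$fluor_frame <- ff
    out[[k]] <- polarity_table(list(img), sub, ff, cfg,
                               sim$config$pixel_size)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
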