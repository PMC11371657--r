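# Synthetic time-lapse microscopy generator.
#
# Emulates the study conditions of the microfluidic experiments: sparse
# surface-attached rod-shaped cells (~0.9 um wide) twitching at ~0.2 um/min
# with rare ~20x single-frame jumps and occasional reversals, a small
# stationary fraction, polar fluorescent foci with
# nonpolar/unipolar/bipolar states, dual-channel acquisition at different
# frame rates sharing one clock, and an erf-shaped cross-channel dye
# gradient that alternates direction at scripted swap times. Every run
# carries complete ground truth so each downstream stage can be validated
# with no external data.
#
# Synthetic images are generated clean: no photobleaching, drift or uneven
# illumination (real data are corrected for these upstream), and scripted
# polarity timelines change only at scripted repolarization events.

#' Scenario configuration for the synthetic generator
#'
#' @param scenario_kind `"alternating_gradient"`, `"taylor_aris"` or
#'   `"switching"`.
#' @param n_cells number of cells.
#' @param field_size image size in pixels, `c(rows, cols)` (y, x).
#' @param pixel_size um per pixel.
#' @param frame_rate_cell cell-channel frame rate (frames/min).
#' @param frame_rate_fluor fluorescence frame rate (frames/min); must divide
#'   `frame_rate_cell` so that every fluorescence frame coincides with a
#'   cell-channel frame (shared acquisition clock).
#' @param duration experiment duration (min); frames cover `[0, duration)`.
#' @param stationary_fraction probability a cell is stationary.
#' @param mean_speed motile-cell speed (um/min).
#' @param jump_speed_factor speed multiplier during single-frame jumps.
#' @param jump_probability_per_frame probability of a jump frame.
#' @param reversal_rate_baseline spontaneous reversal rate (events/min).
#' @param cell_width cell width (um).
#' @param cell_length_range min/max cell length (um).
#' @param focus_sigma polar focus Gaussian width (um).
#' @param noise_model `list(kind = "none")`, `list(kind = "gaussian", sd = )`
#'   or `list(kind = "poisson", scale = )`.
#' @param gradient_params a [gradient_design()] (defaults to a 2 mM dual-flow
#'   source over a 100 um length scale for the alternating scenario).
#' @param swap_times gradient swap times (min), inside `[0, duration)`.
#' @param repolarization_spec optional [repolarization_spec()] of scripted
#'   events.
#' @param rng_seed integer seed; identical config + seed gives identical
#'   output.
#' @param stationary_jitter_sd sub-pixel centroid jitter of stationary cells
#'   (um per frame).
#' @param background,body_intensity cell-channel background and body levels.
#' @param fluor_background,fluor_body,focus_amplitude fluorescence-channel
#'   levels (a.u. in \[0, 1\]).
#' @param focus_inset distance of a polar focus centre from the pole tip (um).
#' @param dye_gain,dye_offset affine dye calibration (intensity =
#'   gain * C + offset).
#' @param leading_pole_bias probability that a motile unipolar cell's bright
#'   pole is its leading pole.
#' @return object of class `scenario_config`.
#' @export
scenario_config <- function(scenario_kind = c("alternating_gradient",
                                              "taylor_aris", "switching"),
                            n_cells = 50,
                            field_size = c(512, 512),
                            pixel_size = 0.1,
                            frame_rate_cell = 7.5,
                            frame_rate_fluor = 0.5,
                            duration = 60,
                            stationary_fraction = 0.075,
                            mean_speed = 0.2,
                            jump_speed_factor = 20,
                            jump_probability_per_frame = 0.01,
                            reversal_rate_baseline = 0.005,
                            cell_width = 0.9,
                            cell_length_range = c(1.8, 3.6),
                            focus_sigma = 0.15,
                            noise_model = list(kind = "none"),
                            gradient_params = NULL,
                            swap_times = numeric(),
                            repolarization_spec = NULL,
                            rng_seed = 1,
                            stationary_jitter_sd = 0.02,
                            background = 0.05,
                            body_intensity = 0.45,
                            fluor_background = 0.02,
                            fluor_body = 0.1,
                            focus_amplitude = 0.5,
                            focus_inset = 0.2,
                            dye_gain = 0.4,
                            dye_offset = 0.05,
                            leading_pole_bias = 0.84) {
  scenario_kind <- match.arg(scenario_kind)
  check_finite(n_cells = n_cells, pixel_size = pixel_size,
               frame_rate_cell = frame_rate_cell,
               frame_rate_fluor = frame_rate_fluor, duration = duration,
               stationary_fraction = stationary_fraction,
               mean_speed = mean_speed, jump_speed_factor = jump_speed_factor,
               jump_probability_per_frame = jump_probability_per_frame,
               reversal_rate_baseline = reversal_rate_baseline,
               cell_width = cell_width, focus_sigma = focus_sigma)
  if (stationary_fraction < 0 || stationary_fraction > 1) {
    stop("stationary_fraction must be in [0, 1]")
  }
  if (frame_rate_fluor > frame_rate_cell) {
    stop("frame_rate_fluor must not exceed frame_rate_cell")
  }
  ratio <- frame_rate_cell / frame_rate_fluor
  if (abs(ratio - round(ratio)) > 1e-9) {
    stop("frame_rate_cell must be an integer multiple of frame_rate_fluor ",
         "(shared acquisition clock)")
  }
  if (any(c(pixel_size, duration, cell_width, cell_length_range,
            focus_sigma) <= 0)) {
    stop("all lengths and durations must be > 0")
  }
  if (length(swap_times) &&
      (any(swap_times < 0) || any(swap_times >= duration))) {
    stop("swap_times must lie inside [0, duration)")
  }
  if (is.null(gradient_params)) {
    gradient_params <- switch(scenario_kind,
      alternating_gradient = gradient_design(C_max = 2, C_min = 0,
                                             V_C = 0.2, dCdx_ref = 0.02,
                                             width_scale = 100),
      taylor_aris = gradient_design(1.16, 0.84, tau = 60, U = 27000,
                                    V_C = 0.2, dCdx_ref = 0.02),
      switching = gradient_design(1.16, 0.84, tau = 1.5, U = 2500))
  }
  structure(mget(names(formals()), environment()),
            class = "scenario_config")
}

#' Scripted repolarization events
#'
#' One row per event the generator must realize: `cell_id`, the fluorescence
#' frame index `fluor_frame` at which the cell's fusion protein re-localizes
#' to its new pole, and whether the event is `correct` (new pole up-gradient)
#' or incorrect.
#'
#' @param cell_id integer cell ids.
#' @param fluor_frame fluorescence frame indices (0-based).
#' @param correct logical.
#' @return data.frame of class `repolarization_spec`.
#' @export
repolarization_spec <- function(cell_id, fluor_frame, correct) {
  df <- data.frame(cell_id = as.integer(cell_id),
                   fluor_frame = as.integer(fluor_frame),
                   correct = as.logical(correct))
  if (anyDuplicated(df$cell_id)) stop("one scripted event per cell")
  class(df) <- c("repolarization_spec", "data.frame")
  df
}

## frame timestamps: k-th frame at k / rate, covering [0, duration)
frame_times <- function(rate, duration) {
  n <- floor(rate * duration + 1e-9)
  (seq_len(n) - 1) / rate
}

#' Simulate one twitching trajectory
#'
#' Persistent motion at `mean_speed` along the body axis with direction
#' reversals as a Poisson process at `reversal_rate_baseline`, single-frame
#' jumps at `jump_speed_factor` times the mean speed, and (for stationary
#' cells) zero commanded displacement plus sub-pixel Gaussian jitter.
#' Positions reflect at the field margins.
#'
#' @param config a [scenario_config()].
#' @param cell_seed integer seed for this cell's random stream.
#' @param init list with `x`, `y` (um), `orientation` (radians, axial),
#'   `length` (um), `stationary` (logical); missing entries are drawn.
#' @param bounds optional `c(xmin, xmax, ymin, ymax)` (um) the centroid
#'   reflects within; defaults to the field minus a margin. The experiment
#'   generator passes each cell's own placement tile here so that the
#'   synthetic monolayer stays solitary (the assay's target population;
#'   dense clusters are out of scope).
#' @return data.frame: `frame`, `t_min`, `x_um`, `y_um`, `orientation_rad`,
#'   `length_um`, `width_um`, `stationary`, `is_reversal_true`.
#' @export
simulate_twitching_track <- function(config, cell_seed, init = list(),
                                     bounds = NULL) {
  stopifnot(inherits(config, "scenario_config"))
  check_finite(cell_seed = cell_seed)
  set.seed(as.integer(cell_seed))
  tt <- frame_times(config$frame_rate_cell, config$duration)
  n <- length(tt)
  dt <- 1 / config$frame_rate_cell
  fw <- config$field_size[2] * config$pixel_size   # x extent
  fh <- config$field_size[1] * config$pixel_size   # y extent
  margin <- max(config$cell_length_range) / 2 + 1
  if (is.null(bounds)) bounds <- c(margin, fw - margin, margin, fh - margin)
  x0 <- if (!is.null(init$x)) init$x else
    stats::runif(1, bounds[1], bounds[2])
  y0 <- if (!is.null(init$y)) init$y else
    stats::runif(1, bounds[3], bounds[4])
  theta <- if (!is.null(init$orientation)) init$orientation
           else stats::runif(1, 0, pi)
  len <- if (!is.null(init$length)) init$length
         else stats::runif(1, config$cell_length_range[1],
                           config$cell_length_range[2])
  stationary <- if (!is.null(init$stationary)) init$stationary
                else stats::runif(1) < config$stationary_fraction
  u <- c(cos(theta), sin(theta))
  x <- y <- numeric(n)
  rev_flag <- logical(n)
  x[1] <- x0; y[1] <- y0
  dir <- sample(c(-1, 1), 1)
  p_rev <- config$reversal_rate_baseline * dt
  for (k in seq_len(n - 1)) {
    if (stationary) {
      dxy <- stats::rnorm(2, 0, config$stationary_jitter_sd)
    } else {
      if (stats::runif(1) < p_rev) {
        dir <- -dir
        rev_flag[k + 1] <- TRUE
      }
      step <- config$mean_speed * dt
      if (stats::runif(1) < config$jump_probability_per_frame) {
        step <- step * config$jump_speed_factor
      }
      dxy <- dir * step * u
    }
    xn <- x[k] + dxy[1]; yn <- y[k] + dxy[2]
    # reflect at the bounds so the body stays inside its own territory
    if (xn < bounds[1] || xn > bounds[2] || yn < bounds[3] || yn > bounds[4]) {
      xn <- min(max(xn, bounds[1]), bounds[2])
      yn <- min(max(yn, bounds[3]), bounds[4])
      dir <- -dir
    }
    x[k + 1] <- xn; y[k + 1] <- yn
  }
  data.frame(frame = seq_len(n) - 1L, t_min = tt, x_um = x, y_um = y,
             orientation_rad = wrap_axial(theta), length_um = len,
             width_um = config$cell_width, stationary = stationary,
             is_reversal_true = rev_flag)
}

## pole tip positions for a pose row; pole 1 is the +axis endpoint
pole_positions <- function(pose) {
  u <- c(cos(pose$orientation_rad), sin(pose$orientation_rad))
  h <- pose$length_um / 2
  list(p1 = c(pose$x_um + h * u[1], pose$y_um + h * u[2]),
       p2 = c(pose$x_um - h * u[1], pose$y_um - h * u[2]),
       u = u)
}

## focus amplitudes (amp1, amp2) implied by a polarity class
polarity_amplitudes <- function(class, amplitude) {
  amp1 <- amplitude * (class %in% c("unipolar_pole1", "bipolar"))
  amp2 <- amplitude * (class %in% c("unipolar_pole2", "bipolar"))
  cbind(amp1 = amp1, amp2 = amp2)
}

## soft-edged spherocylinder footprint as a local patch (rows, cols,
## values); edge softened over ~1 pixel. Patches are accumulated into the
## frame by the caller so the full image is never copied per cell.
spherocylinder_patch <- function(pose, amplitude, pixel_size, dims) {
  half_w <- pose$width_um / 2
  edge <- 0.5 * pixel_size
  pp <- pole_positions(pose)
  # spine endpoints inset by half width so tip-to-tip extent equals length
  inset <- min(half_w, pose$length_um / 2)
  a <- c(pose$x_um, pose$y_um) + (pose$length_um / 2 - inset) * pp$u
  b <- c(pose$x_um, pose$y_um) - (pose$length_um / 2 - inset) * pp$u
  pad <- half_w + 4 * edge
  j0 <- max(1L, floor((min(a[1], b[1]) - pad) / pixel_size) + 1L)
  j1 <- min(dims[2], ceiling((max(a[1], b[1]) + pad) / pixel_size))
  i0 <- max(1L, floor((min(a[2], b[2]) - pad) / pixel_size) + 1L)
  i1 <- min(dims[1], ceiling((max(a[2], b[2]) + pad) / pixel_size))
  if (j1 < j0 || i1 < i0) return(NULL)
  xs <- (seq(j0, j1) - 0.5) * pixel_size
  ys <- (seq(i0, i1) - 0.5) * pixel_size
  px <- matrix(xs, nrow = length(ys), ncol = length(xs), byrow = TRUE)
  py <- matrix(ys, nrow = length(ys), ncol = length(xs))
  ab <- b - a
  len2 <- sum(ab^2)
  if (len2 == 0) {
    d <- sqrt((px - a[1])^2 + (py - a[2])^2)
  } else {
    tproj <- ((px - a[1]) * ab[1] + (py - a[2]) * ab[2]) / len2
    tproj <- pmin(pmax(tproj, 0), 1)
    d <- sqrt((px - (a[1] + tproj * ab[1]))^2 +
              (py - (a[2] + tproj * ab[2]))^2)
  }
  list(rows = i0:i1, cols = j0:j1,
       values = amplitude * stats::pnorm((half_w - d) / edge))
}

## isotropic Gaussian focus at centre (x, y) um, as a patch
focus_patch <- function(x, y, amplitude, sigma, pixel_size, dims) {
  if (amplitude <= 0) return(NULL)
  pad <- 4 * sigma
  j0 <- max(1L, floor((x - pad) / pixel_size) + 1L)
  j1 <- min(dims[2], ceiling((x + pad) / pixel_size))
  i0 <- max(1L, floor((y - pad) / pixel_size) + 1L)
  i1 <- min(dims[1], ceiling((y + pad) / pixel_size))
  if (j1 < j0 || i1 < i0) return(NULL)
  xs <- (seq(j0, j1) - 0.5) * pixel_size
  ys <- (seq(i0, i1) - 0.5) * pixel_size
  gx <- exp(-(xs - x)^2 / (2 * sigma^2))
  gy <- exp(-(ys - y)^2 / (2 * sigma^2))
  list(rows = i0:i1, cols = j0:j1, values = amplitude * outer(gy, gx))
}


apply_noise <- function(img, noise_model) {
  kind <- noise_model$kind %||% "none"
  switch(kind,
    none = img,
    gaussian = img + stats::rnorm(length(img), 0, noise_model$sd),
    poisson = {
      scale <- noise_model$scale
      matrix(stats::rpois(length(img), pmax(img, 0) * scale) / scale,
             nrow = nrow(img))
    },
    stop("unknown noise model: ", kind))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Render one synthetic image frame
#'
#' Renders the cell channel (soft-edged spherocylinder footprints), the
#' fluorescence channel (dim cell bodies plus isotropic Gaussian foci at the
#' bright poles, optionally offset laterally from the centreline) and the
#' dye channel (affine map of the concentration field at each pixel).
#' Overlapping cells are permitted; intensity adds, and overlaps are
#' reported via a message.
#'
#' @param poses data.frame with one row per cell: `x_um`, `y_um`,
#'   `orientation_rad`, `length_um`, `width_um`.
#' @param polarity_states data.frame aligned with `poses`: columns `amp1`,
#'   `amp2` (focus amplitudes) and optional `off1`, `off2` (lateral offsets,
#'   um) and `amp_mid` (mid-cell focus, for cells nearing division).
#' @param field a [concentration_field()] or `NULL` (uniform dye).
#' @param config a [scenario_config()].
#' @param t frame time (min), used to evaluate the field.
#' @param channels subset of `c("cell", "fluor", "dye")`.
#' @return named list of image matrices (`field_size`), values in a.u.
#' @export
render_frame <- function(poses, polarity_states = NULL, field = NULL, config,
                         t = 0, channels = c("cell", "fluor", "dye")) {
  stopifnot(inherits(config, "scenario_config"))
  channels <- match.arg(channels, several.ok = TRUE)
  nr <- config$field_size[1]; nc <- config$field_size[2]
  px <- config$pixel_size
  n <- if (is.null(poses)) 0L else nrow(poses)
  if (n > 1) {
    # crude overlap log: centroid pairs closer than one cell length
    dmat <- as.matrix(stats::dist(cbind(poses$x_um, poses$y_um)))
    close <- sum(dmat[upper.tri(dmat)] < max(poses$length_um))
    if (close > 0) message(sprintf("render_frame: %d potentially overlapping cell pair(s)", close))
  }
  out <- list()
  dims <- c(nr, nc)
  if ("cell" %in% channels) {
    img <- matrix(config$background, nr, nc)
    for (i in seq_len(n)) {
      p <- spherocylinder_patch(poses[i, ], config$body_intensity, px, dims)
      # accumulated inline: the frame matrix is locally owned, so the
      # sub-assignment modifies it without copying the full image per cell
      if (!is.null(p)) img[p$rows, p$cols] <- img[p$rows, p$cols] + p$values
    }
    out$cell <- apply_noise(img, config$noise_model)
  }
  if ("fluor" %in% channels) {
    img <- matrix(config$fluor_background, nr, nc)
    for (i in seq_len(n)) {
      pose <- poses[i, ]
      p <- spherocylinder_patch(pose, config$fluor_body, px, dims)
      if (!is.null(p)) img[p$rows, p$cols] <- img[p$rows, p$cols] + p$values
      if (!is.null(polarity_states)) {
        st <- polarity_states[i, ]
        pp <- pole_positions(pose)
        perp <- c(-pp$u[2], pp$u[1])
        inset <- config$focus_inset
        for (pole in 1:2) {
          amp <- st[[paste0("amp", pole)]] %||% 0
          if (is.na(amp) || amp <= 0) next
          off <- st[[paste0("off", pole)]] %||% 0
          if (is.null(off) || is.na(off)) off <- 0
          tip <- if (pole == 1) pp$p1 else pp$p2
          ctr <- tip - (if (pole == 1) 1 else -1) * inset * pp$u + off * perp
          p <- focus_patch(ctr[1], ctr[2], amp, config$focus_sigma, px, dims)
          if (!is.null(p)) img[p$rows, p$cols] <- img[p$rows, p$cols] + p$values
        }
        amp_mid <- st[["amp_mid"]] %||% 0
        if (!is.null(amp_mid) && !is.na(amp_mid) && amp_mid > 0) {
          p <- focus_patch(pose$x_um, pose$y_um, amp_mid,
                           config$focus_sigma, px, dims)
          if (!is.null(p)) img[p$rows, p$cols] <- img[p$rows, p$cols] + p$values
        }
      }
    }
    out$fluor <- apply_noise(img, config$noise_model)
  }
  if ("dye" %in% channels) {
    if (is.null(field)) {
      img <- matrix(config$dye_offset, nr, nc)
    } else {
      ys <- (seq_len(nr) - 0.5) * px
      Cy <- field$evaluate(ys, t)
      img <- matrix(config$dye_gain * Cy + config$dye_offset, nr, nc)
    }
    out$dye <- apply_noise(img, config$noise_model)
  }
  out
}

#' Simulate a complete experiment with ground truth
#'
#' Simulates all trajectories and polarity timelines for a scenario and
#' returns them with the analytic concentration field. Scripted
#' repolarization events are realized as sustained unipolar re-localizations
#' at the event frame (the scripted cell is forced stationary, its initial
#' polarity is drawn from the classes other than unipolar-at-the-new-pole,
#' and the new pole is the up-gradient pole for `correct` events under the
#' post-swap gradient orientation). Images are rendered on demand with
#' [render_sim_frame()] / [write_experiment()] so that long runs never hold
#' a full stack in memory.
#'
#' @param config a [scenario_config()].
#' @return object of class `twitch_sim`: `config`, `field`, frame-time
#'   vectors, and `ground_truth` (`poses`, `polarity`, `events`).
#' @export
simulate_experiment <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(as.integer(config$rng_seed))
  t_cell <- frame_times(config$frame_rate_cell, config$duration)
  t_fluor <- frame_times(config$frame_rate_fluor, config$duration)
  stride <- as.integer(round(config$frame_rate_cell / config$frame_rate_fluor))
  spec <- config$repolarization_spec
  if (!is.null(spec)) {
    if (any(spec$cell_id < 1 | spec$cell_id > config$n_cells)) {
      stop("scripted cell ids outside 1..n_cells")
    }
    if (any(spec$fluor_frame < 0 | spec$fluor_frame > length(t_fluor) - 2)) {
      stop("scripted event frames must leave at least one later fluorescence frame")
    }
  }
  field_kind <- switch(config$scenario_kind,
                       alternating_gradient = "alternating_gradient",
                       taylor_aris = "taylor_aris",
                       switching = "switching")
  fh <- config$field_size[1] * config$pixel_size
  field <- concentration_field(config$gradient_params, field_kind,
                               swap_times = config$swap_times, mid = fh / 2)

  # jittered-grid initial placement keeps the monolayer sparse
  ngrid <- ceiling(sqrt(config$n_cells))
  fw <- config$field_size[2] * config$pixel_size
  margin <- max(config$cell_length_range) / 2 + 1
  gx <- seq(margin, fw - margin, length.out = ngrid)
  gy <- seq(margin, fh - margin, length.out = ngrid)
  grid <- expand.grid(x = gx, y = gy)
  grid <- grid[sample(nrow(grid), config$n_cells), ]
  spacing <- if (ngrid > 1) min(gx[2] - gx[1], gy[2] - gy[1]) else
    min(fw, fh) / 2
  # keep jittered tips inside the field so profiles never sample outside
  jit_amp <- max(0, min(spacing * 0.15,
                        margin - max(config$cell_length_range) / 2 - 0.4))
  scripted_ids <- if (is.null(spec)) integer() else spec$cell_id
  axis_theta <- pi / 2  # gradient axis is +y
  # each cell moves within its own placement tile, shrunk so that cell
  # bodies (and the profiler's sampling band) from neighbouring tiles can
  # never approach one another: the monolayer stays solitary by
  # construction
  tile_margin <- max(config$cell_length_range) / 2 + 0.5
  tile_half <- max(spacing / 2 - tile_margin, 0.1)
  tracks <- vector("list", config$n_cells)
  for (id in seq_len(config$n_cells)) {
    scripted <- id %in% scripted_ids
    init <- list(
      x = grid$x[id] + stats::runif(1, -jit_amp, jit_amp),
      y = grid$y[id] + stats::runif(1, -jit_amp, jit_amp),
      orientation = if (scripted) {
        wrap_axial(axis_theta + stats::runif(1, -0.3, 0.3))
      } else stats::runif(1, 0, pi),
      stationary = if (scripted) TRUE else
        stats::runif(1) < config$stationary_fraction)
    bounds <- c(
      max(grid$x[id] - tile_half, margin),
      min(grid$x[id] + tile_half, fw - margin),
      max(grid$y[id] - tile_half, margin),
      min(grid$y[id] + tile_half, fh - margin))
    init$x <- min(max(init$x, bounds[1]), bounds[2])
    init$y <- min(max(init$y, bounds[3]), bounds[4])
    cell_seed <- (as.integer(config$rng_seed) + id * 1009L) %% 2147483587L
    tr <- simulate_twitching_track(config, cell_seed, init, bounds)
    tr$cell_id <- id
    tracks[[id]] <- tr
  }
  poses <- do.call(rbind, tracks)
  poses$motility_class_true <- ifelse(poses$stationary, "stationary", "motile")

  # polarity timelines on the fluorescence clock
  set.seed(as.integer(config$rng_seed) + 7919L)
  n_f <- length(t_fluor)
  classes <- c("nonpolar", "unipolar_pole1", "unipolar_pole2", "bipolar")
  pol <- vector("list", config$n_cells)
  events <- list()
  for (id in seq_len(config$n_cells)) {
    tr <- tracks[[id]]
    scripted <- id %in% scripted_ids
    if (scripted) {
      ev <- spec[spec$cell_id == id, ]
      t_ev <- t_fluor[ev$fluor_frame + 1]
      swaps_before <- config$swap_times[config$swap_times <= t_ev]
      if (length(swaps_before) == 0) {
        stop("scripted event for cell ", id, " precedes every gradient swap")
      }
      sgn <- field$epoch_sign(t_ev)
      pose_ev <- tr[tr$t_min <= t_ev, ][sum(tr$t_min <= t_ev), ]
      pp <- pole_positions(pose_ev)
      C1 <- field$evaluate(pp$p1[2], t_ev)   # gradient axis = y
      C2 <- field$evaluate(pp$p2[2], t_ev)
      if (C1 == C2) stop("scripted cell ", id, " has poles at equal concentration")
      up_pole <- if (C1 > C2) 1L else 2L
      new_pole <- if (ev$correct) up_pole else 3L - up_pole
      init_class <- sample(c("nonpolar", "bipolar",
                             paste0("unipolar_pole", 3L - new_pole)), 1)
      cls <- rep(init_class, n_f)
      # sustained re-localization from the event frame to the next swap
      later_swaps <- config$swap_times[config$swap_times > t_ev]
      end_f <- if (length(later_swaps)) {
        sum(t_fluor < later_swaps[1])
      } else n_f
      cls[(ev$fluor_frame + 1):end_f] <- paste0("unipolar_pole", new_pole)
      events[[length(events) + 1]] <- data.frame(
        cell_id = id, fluor_frame = ev$fluor_frame,
        cell_frame = ev$fluor_frame * stride, t_min = t_ev,
        trigger = "polarity_first", initial_polarity = sub("_pole[12]", "", init_class),
        new_leading_pole = new_pole,
        direction_call = if (ev$correct) "correct" else "incorrect",
        stringsAsFactors = FALSE)
    } else if (!tr$stationary[1]) {
      # motile: unipolar at the leading pole with probability
      # leading_pole_bias, fixed over the track (timelines change only at
      # scripted events so that event-free runs are genuinely event-free)
      pp <- pole_positions(tr[1, ])
      drift <- c(tr$x_um[nrow(tr)] - tr$x_um[1], tr$y_um[nrow(tr)] - tr$y_um[1])
      lead <- if (sum(drift * pp$u) >= 0) 1L else 2L
      bright <- if (stats::runif(1) < config$leading_pole_bias) lead else 3L - lead
      cls <- rep(paste0("unipolar_pole", bright), n_f)
    } else {
      cls <- rep(sample(classes, 1, prob = c(0.30, 0.275, 0.275, 0.15)), n_f)
    }
    pol[[id]] <- data.frame(cell_id = id, fluor_frame = seq_len(n_f) - 1L,
                            t_min = t_fluor, class_true = cls,
                            stringsAsFactors = FALSE)
  }
  polarity <- do.call(rbind, pol)
  events <- if (length(events)) do.call(rbind, events) else
    data.frame(cell_id = integer(), fluor_frame = integer(),
               cell_frame = integer(), t_min = numeric(), trigger = character(),
               initial_polarity = character(), new_leading_pole = integer(),
               direction_call = character(), stringsAsFactors = FALSE)
  structure(list(config = config, field = field, t_cell = t_cell,
                 t_fluor = t_fluor, fluor_stride = stride,
                 ground_truth = list(poses = poses, polarity = polarity,
                                     events = events)),
            class = "twitch_sim")
}

#' Render a frame of a simulated experiment on demand
#'
#' @param sim a [simulate_experiment()] result.
#' @param frame cell-channel frame index (0-based). For the fluorescence and
#'   dye channels the frame must coincide with a fluorescence timestamp.
#' @param channels subset of `c("cell", "fluor", "dye")`.
#' @return named list of image matrices.
#' @export
render_sim_frame <- function(sim, frame, channels = c("cell", "fluor", "dye")) {
  stopifnot(inherits(sim, "twitch_sim"))
  channels <- match.arg(channels, several.ok = TRUE)
  gt <- sim$ground_truth
  poses <- gt$poses[gt$poses$frame == frame, ]
  t <- sim$t_cell[frame + 1]
  states <- NULL
  if (any(channels %in% c("fluor"))) {
    if (frame %% sim$fluor_stride != 0) {
      stop("frame ", frame, " has no coincident fluorescence acquisition")
    }
    ff <- frame %/% sim$fluor_stride
    pf <- gt$polarity[gt$polarity$fluor_frame == ff, ]
    cls <- pf$class_true[match(poses$cell_id, pf$cell_id)]
    states <- as.data.frame(polarity_amplitudes(cls,
                                                sim$config$focus_amplitude))
  }
  # deterministic per-frame noise stream
  set.seed((as.integer(sim$config$rng_seed) + 104729L * (frame + 1L)) %%
             2147483587L)
  render_frame(poses, states, sim$field, sim$config, t, channels)
}

#' Write a simulated experiment to disk
#'
#' Writes one multi-page TIFF per channel (page = frame), the ground-truth
#' tables as tab-delimited text, and a YAML metadata sidecar (seed, units,
#' frame rates).
#'
#' @param sim a [simulate_experiment()] result.
#' @param dir output directory (created if needed).
#' @param channels channels to write.
#' @param cell_frames which cell-channel frames to write (default: the
#'   frames coincident with fluorescence acquisitions, which bounds the
#'   stack size for long runs; pass `"all"` for every frame).
#' @return `dir`, invisibly.
#' @export
write_experiment <- function(sim, dir, channels = c("cell", "fluor", "dye"),
                             cell_frames = "fluor") {
  stopifnot(inherits(sim, "twitch_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  frames_cell <- if (identical(cell_frames, "all")) {
    seq_along(sim$t_cell) - 1L
  } else {
    (seq_along(sim$t_fluor) - 1L) * sim$fluor_stride
  }
  clip01 <- function(m) pmin(pmax(m, 0), 1)
  if ("cell" %in% channels) {
    pages <- lapply(frames_cell, function(f)
      clip01(render_sim_frame(sim, f, "cell")$cell))
    tiff::writeTIFF(pages, file.path(dir, "cell_channel.tif"),
                    bits.per.sample = 16)
  }
  for (ch in intersect(channels, c("fluor", "dye"))) {
    pages <- lapply((seq_along(sim$t_fluor) - 1L) * sim$fluor_stride,
                    function(f) clip01(render_sim_frame(sim, f, ch)[[ch]]))
    tiff::writeTIFF(pages, file.path(dir, paste0(ch, "_channel.tif")),
                    bits.per.sample = 16)
  }
  gt <- sim$ground_truth
  utils::write.table(gt$poses, file.path(dir, "ground_truth_poses.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(gt$polarity, file.path(dir, "ground_truth_polarity.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(gt$events, file.path(dir, "ground_truth_events.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  meta <- list(seed = sim$config$rng_seed,
               scenario_kind = sim$config$scenario_kind,
               units = list(length = "um", time = "min", concentration = "mM",
                            angle = "radians"),
               pixel_size_um = sim$config$pixel_size,
               frame_rate_cell_per_min = sim$config$frame_rate_cell,
               frame_rate_fluor_per_min = sim$config$frame_rate_fluor,
               duration_min = sim$config$duration,
               swap_times_min = as.list(sim$config$swap_times),
               cell_frames_written = if (identical(cell_frames, "all"))
                 "all" else "fluor-coincident")
  yaml::write_yaml(meta, file.path(dir, "metadata.yaml"))
  invisible(dir)
}

#' Read a multi-page TIFF stack as a list of matrices
#'
#' @param path TIFF file.
#' @return list of numeric matrices (values in \[0, 1\]).
#' @export
read_stack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  lapply(pages, function(p) if (length(dim(p)) == 3) p[, , 1] else p)
}
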