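# Detection and classification of repolarization events in stationary
# cells exposed to an alternating chemoattractant gradient.
#
# A repolarization event occurs when a stationary cell, after the gradient
# swaps direction, either (A) develops a sustained unipolar localization at
# a pole different from its initial localization, or (B) moves off in a
# consistent direction before any observable change in localization. The
# event is "correct" when the new leading pole sits at the higher
# concentration under the new gradient orientation. A battery of rules
# guards against false positives: a stationarity requirement along the
# gradient axis, an initial-polarity assignment over the frames preceding
# the swap, and a veto for poles that already carried a unipolar
# localization before the swap.

#' Gradient timeline for an alternating-gradient experiment
#'
#' @param swap_times gradient swap times (min), strictly increasing.
#' @param duration experiment duration (min).
#' @param frame_rate_cell,frame_rate_fluor frame rates (frames/min);
#'   the cell rate must be an integer multiple of the fluorescence rate.
#' @param field a [concentration_field()] for the device (gradient axis is
#'   the field's position coordinate, +y by default).
#' @param dead_zone_halfwidth half-width of the centreline dead zone (um)
#'   inside which temporal changes are not assignable; default
#'   `0.1 * width_scale` of the field's design.
#' @return object of class `gradient_timeline` with epoch bookkeeping on
#'   both frame clocks.
#' @export
gradient_timeline <- function(swap_times, duration, frame_rate_cell = 7.5,
                              frame_rate_fluor = 0.5, field,
                              dead_zone_halfwidth = NULL) {
  stopifnot(inherits(field, "concentration_field"))
  if (length(swap_times) > 1 && is.unsorted(swap_times, strictly = TRUE)) {
    stop("swap_times must be strictly increasing")
  }
  stride <- frame_rate_cell / frame_rate_fluor
  if (abs(stride - round(stride)) > 1e-9) {
    stop("frame_rate_cell must be an integer multiple of frame_rate_fluor")
  }
  if (is.null(dead_zone_halfwidth)) {
    dead_zone_halfwidth <- 0.1 * field$design$width_scale
  }
  t_cell <- frame_times(frame_rate_cell, duration)
  t_fluor <- frame_times(frame_rate_fluor, duration)
  bounds <- c(0, swap_times, duration)
  epochs <- data.frame(
    start_min = bounds[-length(bounds)],
    end_min = bounds[-1],
    sign = field$epoch_sign(bounds[-length(bounds)]))
  structure(list(swap_times = swap_times, duration = duration,
                 frame_rate_cell = frame_rate_cell,
                 frame_rate_fluor = frame_rate_fluor,
                 stride = as.integer(round(stride)),
                 t_cell = t_cell, t_fluor = t_fluor, epochs = epochs,
                 field = field, dead_zone_halfwidth = dead_zone_halfwidth),
            class = "gradient_timeline")
}

## classes that carry polar information (everything else is treated as a
## missing observation; mid-cell localizations are never polar signal)
polar_classes <- c("nonpolar", "unipolar_pole1", "unipolar_pole2", "bipolar")

## collapse a per-pole class to its polarity mode
polarity_mode <- function(class) sub("_pole[12]", "", class)

#' Stationarity check over the monitoring window
#'
#' The monitoring window runs from the frame after the last cell-channel
#' frame of the initial gradient until `event_frame`, extended to at least
#' `min_preceding` frames before the event. Displacements are projected on
#' the gradient axis; the cell fails if (a) it moves more than half a cell
#' width in the same direction on two consecutive frames, or (b) its net
#' excursion from the window start exceeds one cell width at any frame.
#'
#' @param traj one cell's trajectory (`frame`, `x_um`, `y_um`).
#' @param timeline a [gradient_timeline()].
#' @param event_frame candidate event frame (cell-channel clock, 0-based).
#' @param swap_index which gradient swap precedes the event (1-based).
#' @param cell_width nominal cell width (um).
#' @param min_preceding minimum frames monitored before the event.
#' @param axis gradient axis, `"y"`, `"x"` or a unit vector.
#' @return list `pass` (logical) and `reason` (`NA`, `"no_window"`,
#'   `"consecutive_steps"` or `"net_excursion"`).
#' @export
stationary_window_check <- function(traj, timeline, event_frame,
                                    swap_index = 1, cell_width = 0.9,
                                    min_preceding = 3, axis = "y") {
  g <- axis_unit_vector(axis)
  t_swap <- timeline$swap_times[swap_index]
  # first cell frame at/after the swap = frame after the last frame of the
  # initial gradient
  w_start <- match(TRUE, timeline$t_cell >= t_swap) - 1L
  w_start <- min(w_start, event_frame - min_preceding)
  w_start <- max(w_start, 0L)
  sel <- traj$frame >= w_start & traj$frame <= event_frame
  if (sum(sel) < 2) return(list(pass = FALSE, reason = "no_window"))
  tr <- traj[sel, ][order(traj$frame[sel]), ]
  proj <- (tr$x_um - tr$x_um[1]) * g[1] + (tr$y_um - tr$y_um[1]) * g[2]
  steps <- diff(proj)
  if (length(steps) >= 2) {
    big <- abs(steps) > cell_width / 2
    same <- sign(steps[-1]) == sign(steps[-length(steps)])
    if (any(big[-1] & big[-length(big)] & same)) {
      return(list(pass = FALSE, reason = "consecutive_steps"))
    }
  }
  if (any(abs(proj) > cell_width)) {
    return(list(pass = FALSE, reason = "net_excursion"))
  }
  list(pass = TRUE, reason = NA_character_)
}

#' Initial polarity before a gradient swap
#'
#' Majority polarity mode over the (up to) four fluorescence frames
#' preceding the appearance of the final gradient orientation; a 2-2 tie is
#' broken by the frame immediately preceding the swap. Frames without a
#' usable class (mid-cell exclusions, invalid profiles) are treated as
#' missing; if a division (`excluded_midcell`) is flagged, only frames
#' after it are counted. Unresolvable cases give `"not_assignable"`.
#'
#' @param pol one cell's polarity series (`fluor_frame`, `polarity_class`).
#' @param timeline a [gradient_timeline()].
#' @param swap_index 1-based swap index.
#' @return list: `mode` (`"nonpolar"`, `"unipolar"`, `"bipolar"` or
#'   `"not_assignable"`), `unipolar_pole` (1, 2 or NA), `post_division`
#'   (logical), `n_frames_used`.
#' @export
initial_polarity <- function(pol, timeline, swap_index = 1) {
  t_swap <- timeline$swap_times[swap_index]
  pre <- pol[timeline$t_fluor[pol$fluor_frame + 1] < t_swap, ]
  pre <- pre[order(pre$fluor_frame), ]
  post_division <- FALSE
  div <- which(pre$polarity_class == "excluded_midcell")
  if (length(div)) {
    post_division <- max(div) > nrow(pre) - 4  # division among recent frames
    pre <- pre[seq_len(nrow(pre)) > max(div), , drop = FALSE]
  }
  pre <- utils::tail(pre, 4)
  usable <- pre$polarity_class %in% polar_classes
  cls <- pre$polarity_class[usable]
  if (length(cls) == 0) {
    return(list(mode = "not_assignable", unipolar_pole = NA_integer_,
                post_division = post_division, n_frames_used = 0L))
  }
  modes <- polarity_mode(cls)
  tab <- table(modes)
  top <- names(tab)[tab == max(tab)]
  mode <- if (length(top) == 1) top else {
    # tie: the mode of the frame immediately preceding the swap
    polarity_mode(cls[length(cls)])
  }
  pole <- NA_integer_
  if (mode == "unipolar") {
    uni <- cls[polarity_mode(cls) == "unipolar"]
    pole_tab <- table(uni)
    win <- names(pole_tab)[which.max(pole_tab)]
    pole <- if (win == "unipolar_pole1") 1L else 2L
  }
  list(mode = mode, unipolar_pole = pole, post_division = post_division,
       n_frames_used = length(cls))
}

## poles vetoed as "new leading pole": unipolar there in >= 2 of the 4
## pre-swap fluorescence frames, or in the frame immediately preceding
vetoed_poles <- function(pol, timeline, swap_index) {
  t_swap <- timeline$swap_times[swap_index]
  pre <- pol[timeline$t_fluor[pol$fluor_frame + 1] < t_swap, ]
  pre <- pre[order(pre$fluor_frame), ]
  last4 <- utils::tail(pre$polarity_class, 4)
  lastc <- utils::tail(pre$polarity_class, 1)
  vet <- integer()
  for (p in 1:2) {
    lab <- paste0("unipolar_pole", p)
    if (sum(last4 == lab) >= 2 || identical(lastc, lab)) vet <- c(vet, p)
  }
  vet
}

#' Detect a repolarization event for one cell after one gradient swap
#'
#' Scans the epoch following swap `swap_index`. Trigger A (polarity-first)
#' fires at the first fluorescence frame carrying a unipolar class at a
#' non-vetoed pole that holds in at least 2 of the 4 consecutive frames
#' starting there; trigger B (movement-first) fires at the first
#' cell-channel frame starting two consecutive same-direction steps along
#' the gradient axis of at least one cell width each. The earlier trigger
#' that also passes [stationary_window_check()] defines the event.
#'
#' @param pol one cell's polarity series (`fluor_frame`, `polarity_class`).
#' @param traj the cell's trajectory (`frame`, `t_min`, `x_um`, `y_um`,
#'   `orientation_rad`, `length_um`).
#' @param timeline a [gradient_timeline()].
#' @param swap_index 1-based swap index.
#' @param cell_width nominal cell width (um) used by both the stationarity
#'   rules and trigger B.
#' @param min_preceding frames monitored before the event.
#' @param axis gradient axis.
#' @return a one-row data.frame (see [find_repolarization_events()]) or
#'   `NULL` when no event is found.
#' @export
detect_event <- function(pol, traj, timeline, swap_index = 1,
                         cell_width = 0.9, min_preceding = 3, axis = "y") {
  t_swap <- timeline$swap_times[swap_index]
  t_next <- if (swap_index < length(timeline$swap_times)) {
    timeline$swap_times[swap_index + 1]
  } else timeline$duration
  init <- initial_polarity(pol, timeline, swap_index)
  vet <- vetoed_poles(pol, timeline, swap_index)
  g <- axis_unit_vector(axis)

  # --- trigger A: sustained unipolar localization at a new pole ---
  in_epoch <- timeline$t_fluor[pol$fluor_frame + 1] >= t_swap &
    timeline$t_fluor[pol$fluor_frame + 1] < t_next
  post <- pol[in_epoch, ]
  post <- post[order(post$fluor_frame), ]
  candA <- NULL
  for (i in seq_len(nrow(post))) {
    cls <- post$polarity_class[i]
    if (!(cls %in% c("unipolar_pole1", "unipolar_pole2"))) next
    p <- if (cls == "unipolar_pole1") 1L else 2L
    if (p %in% vet) next
    if (!is.na(init$unipolar_pole) && p == init$unipolar_pole) next
    win <- post$polarity_class[i:min(i + 3, nrow(post))]
    if (sum(win == cls) >= 2) {
      candA <- list(fluor_frame = post$fluor_frame[i],
                    cell_frame = post$fluor_frame[i] * timeline$stride,
                    t = timeline$t_fluor[post$fluor_frame[i] + 1],
                    pole = p, trigger = "polarity_first")
      break
    }
  }

  # --- trigger B: moving off at >= one cell width per frame ---
  candB <- NULL
  sel <- traj$t_min >= t_swap & traj$t_min < t_next
  tr <- traj[sel, ][order(traj$frame[sel]), ]
  if (nrow(tr) >= 3) {
    proj <- (tr$x_um * g[1] + tr$y_um * g[2])
    steps <- diff(proj)
    for (k in seq_len(length(steps) - 1)) {
      if (abs(steps[k]) >= cell_width && abs(steps[k + 1]) >= cell_width &&
          sign(steps[k]) == sign(steps[k + 1])) {
        u <- c(cos(tr$orientation_rad[k]), sin(tr$orientation_rad[k]))
        movdir <- sign(steps[k]) # along gradient axis
        pole <- if (sum(u * g) * movdir > 0) 1L else 2L
        if (!(pole %in% vet)) {
          candB <- list(fluor_frame = NA_integer_, cell_frame = tr$frame[k],
                        t = tr$t_min[k], pole = pole,
                        trigger = "movement_first")
        }
        break
      }
    }
  }

  cands <- Filter(Negate(is.null), list(candA, candB))
  if (length(cands) == 0) return(NULL)
  cands <- cands[order(vapply(cands, `[[`, 0, "t"))]
  for (cand in cands) {
    chk <- stationary_window_check(traj, timeline, cand$cell_frame,
                                   swap_index, cell_width, min_preceding,
                                   axis)
    if (!chk$pass) next
    pose <- traj[which.min(abs(traj$frame - cand$cell_frame)), ]
    call <- classify_correctness(cand$pole, pose, timeline, cand$t, axis)
    temporal <- assign_temporal_change(pose, timeline, swap_index, axis)
    return(data.frame(cell_id = traj$cell_id[1] %||% NA_integer_,
                      event_frame = cand$cell_frame,
                      fluor_frame = cand$fluor_frame,
                      t_min = cand$t, trigger = cand$trigger,
                      initial_polarity = init$mode,
                      new_leading_pole = cand$pole,
                      direction_call = call,
                      temporal_change = temporal,
                      post_division = init$post_division,
                      swap_index = swap_index,
                      stringsAsFactors = FALSE))
  }
  NULL
}

#' Correctness of a repolarization event
#'
#' `"correct"` when the new leading pole's position experiences a higher
#' concentration than the opposite pole under the current epoch's field,
#' `"incorrect"` otherwise, `NA` (with a message) when the two poles sit at
#' equal concentration.
#'
#' @param new_pole 1 or 2.
#' @param pose one-row pose (`x_um`, `y_um`, `orientation_rad`,
#'   `length_um`).
#' @param timeline a [gradient_timeline()].
#' @param t event time (min).
#' @param axis gradient axis.
#' @return `"correct"`, `"incorrect"` or `NA`.
#' @export
classify_correctness <- function(new_pole, pose, timeline, t, axis = "y") {
  g <- axis_unit_vector(axis)
  pp <- pole_positions(pose)
  C1 <- timeline$field$evaluate(sum(pp$p1 * g), t)
  C2 <- timeline$field$evaluate(sum(pp$p2 * g), t)
  if (C1 == C2) {
    message("poles at equal concentration; correctness not classifiable")
    return(NA_character_)
  }
  up <- if (C1 > C2) 1L else 2L
  if (new_pole == up) "correct" else "incorrect"
}

#' Temporal concentration change experienced at a swap
#'
#' Cells sitting at pre-swap concentration below `C_max / 2` experience a
#' step-up when the gradient flips, those above a step-down; cells within
#' the centreline dead zone (where the change is too small to resolve) are
#' `"not_assignable"`.
#'
#' @param pose one-row pose (`x_um`, `y_um`).
#' @param timeline a [gradient_timeline()].
#' @param swap_index 1-based swap index.
#' @param axis gradient axis.
#' @return `"step_up"`, `"step_down"` or `"not_assignable"`.
#' @export
assign_temporal_change <- function(pose, timeline, swap_index = 1,
                                   axis = "y") {
  g <- axis_unit_vector(axis)
  posn <- pose$x_um * g[1] + pose$y_um * g[2]
  if (abs(posn - timeline$field$mid) < timeline$dead_zone_halfwidth) {
    return("not_assignable")
  }
  t_swap <- timeline$swap_times[swap_index]
  C_pre <- timeline$field$evaluate(posn, t_swap - 1e-9)
  half <- timeline$field$design$C_max / 2
  if (C_pre < half) "step_up" else if (C_pre > half) "step_down" else
    "not_assignable"
}

#' Detect repolarization events for every cell and swap
#'
#' @param polarity polarity table (`cell_id`, `fluor_frame`,
#'   `polarity_class`).
#' @param poses trajectory table (`cell_id`, `frame`, `t_min`, `x_um`,
#'   `y_um`, `orientation_rad`, `length_um`).
#' @param timeline a [gradient_timeline()].
#' @param swap_indices which swaps to scan (default all).
#' @param ... passed to [detect_event()].
#' @return data.frame of events (possibly empty), one row per cell and
#'   swap; columns as in [detect_event()].
#' @export
find_repolarization_events <- function(polarity, poses, timeline,
                                       swap_indices = NULL, ...) {
  if (is.null(swap_indices)) swap_indices <- seq_along(timeline$swap_times)
  ids <- sort(unique(poses$cell_id))
  out <- list()
  for (id in ids) {
    pol <- polarity[polarity$cell_id == id, ]
    tr <- poses[poses$cell_id == id, ]
    if (nrow(pol) == 0 || nrow(tr) < 2) next
    for (s in swap_indices) {
      ev <- detect_event(pol, tr, timeline, swap_index = s, ...)
      if (!is.null(ev)) out[[length(out) + 1]] <- ev
    }
  }
  if (length(out) == 0) {
    return(data.frame(cell_id = integer(), event_frame = integer(),
                      fluor_frame = integer(), t_min = numeric(),
                      trigger = character(), initial_polarity = character(),
                      new_leading_pole = integer(),
                      direction_call = character(),
                      temporal_change = character(),
                      post_division = logical(), swap_index = integer(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Summarise classified repolarization events
#'
#' Counts and proportions of correct vs incorrect events, overall and
#' stratified by initial polarity and by temporal change, with Wilson
#' confidence intervals on the correct proportion and exact two-sided
#' binomial tests against equal abundance.
#'
#' @param events events data.frame with `direction_call` and (optionally)
#'   `initial_polarity`, `temporal_change` columns; or `NULL`/empty.
#' @param conf confidence level for the proportion intervals.
#' @return object of class `event_summary`: `overall` (list with counts,
#'   `ratio`, CI and p-value), `by_initial_polarity` and
#'   `by_temporal_change` data.frames.
#' @export
summarize_events <- function(events, conf = 0.95) {
  empty <- structure(list(overall = NULL, by_initial_polarity = NULL,
                          by_temporal_change = NULL, n_events = 0L),
                     class = "event_summary")
  if (is.null(events) || nrow(events) == 0) return(empty)
  ok <- !is.na(events$direction_call)
  events <- events[ok, , drop = FALSE]
  if (nrow(events) == 0) return(empty)
  tally <- function(df) {
    nc <- sum(df$direction_call == "correct")
    ni <- sum(df$direction_call == "incorrect")
    n <- nc + ni
    ci <- if (n > 0) proportion_ci(nc, n, conf) else c(NA, NA)
    p <- if (n > 0) exact_binomial_test(nc, n, 0.5, "two.sided") else NA
    list(n_correct = nc, n_incorrect = ni,
         ratio = if (ni > 0) nc / ni else Inf,
         prop_correct = if (n > 0) nc / n else NA_real_,
         ci_low = ci[1], ci_high = ci[2], p_value = p)
  }
  strat <- function(col) {
    if (!col %in% names(events)) return(NULL)
    lv <- unique(events[[col]])
    rows <- lapply(lv, function(l) {
      r <- tally(events[events[[col]] == l, , drop = FALSE])
      data.frame(group = l, n_correct = r$n_correct,
                 n_incorrect = r$n_incorrect, prop_correct = r$prop_correct,
                 ci_low = r$ci_low, ci_high = r$ci_high,
                 p_value = r$p_value, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  }
  structure(list(overall = tally(events),
                 by_initial_polarity = strat("initial_polarity"),
                 by_temporal_change = strat("temporal_change"),
                 n_events = nrow(events)),
            class = "event_summary")
}

#' @export
print.event_summary <- function(x, ...) {
  if (x$n_events == 0) {
    cat("No classified repolarization events.\n")
    return(invisible(x))
  }
  o <- x$overall
  cat(sprintf("Repolarization events: %d correct, %d incorrect (ratio %.2g)\n",
              o$n_correct, o$n_incorrect, o$ratio))
  cat(sprintf("  correct proportion %.3f [%.3f, %.3f], exact binomial P = %.3g\n",
              o$prop_correct, o$ci_low, o$ci_high, o$p_value))
  for (nm in c("by_initial_polarity", "by_temporal_change")) {
    if (!is.null(x[[nm]])) {
      cat(" ", gsub("_", " ", sub("by_", "by ", nm)), ":\n")
      print(x[[nm]], row.names = FALSE)
    }
  }
  invisible(x)
}
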