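# Repolarization event rules: stationarity, initial polarity, triggers,
# veto, correctness and temporal-change assignment.

tl <- demo_timeline()  # swap at 45 min, 90 min experiment, axis +y, mid 50

test_that("stationarity rules monitor movement along the gradient axis", {
  tr <- still_track(tl, y = 30)
  expect_true(stationary_window_check(tr, tl, 400)$pass)
  # two consecutive +0.5 um steps along the gradient exceed half a width
  tr_a <- tr
  k <- match(360, tr_a$frame)
  tr_a$y_um[(k + 1):nrow(tr_a)] <- tr_a$y_um[(k + 1):nrow(tr_a)] + 0.5
  tr_a$y_um[(k + 2):nrow(tr_a)] <- tr_a$y_um[(k + 2):nrow(tr_a)] + 0.5
  chk <- stationary_window_check(tr_a, tl, 400)
  expect_false(chk$pass)
  expect_equal(chk$reason, "consecutive_steps")
  # 3 um of drift orthogonal to the gradient axis is ignored
  tr_x <- tr
  tr_x$x_um <- tr_x$x_um + seq(0, 3, length.out = nrow(tr_x))
  expect_true(stationary_window_check(tr_x, tl, 400)$pass)
  # cumulative excursion beyond one cell width (within the monitoring
  # window) fails, even when each individual step is small
  tr_b <- tr
  ramp <- tr_b$frame >= 350 & tr_b$frame <= 390
  tr_b$y_um[ramp] <- tr_b$y_um[ramp] + seq(0, 1.2, length.out = sum(ramp))
  tr_b$y_um[tr_b$frame > 390] <- tr_b$y_um[tr_b$frame > 390] + 1.2
  expect_equal(stationary_window_check(tr_b, tl, 400)$reason,
               "net_excursion")
  expect_false(stationary_window_check(tr[tr$frame < 300, ], tl, 400)$pass)
})

test_that("initial polarity is the majority of the four pre-swap frames,
           with ties broken by the last frame", {
  n_f <- length(tl$t_fluor)
  mk <- function(last4) {
    cls <- rep("nonpolar", n_f)
    # fluor frames 19..22 (t = 38..44) are the last four before the swap
    cls[20:23] <- last4
    polarity_series(tl, cls)
  }
  ip <- initial_polarity(mk(c("bipolar", "bipolar", "bipolar",
                              "unipolar_pole1")), tl)
  expect_equal(ip$mode, "bipolar")
  ip2 <- initial_polarity(mk(c("unipolar_pole1", "unipolar_pole1",
                               "nonpolar", "nonpolar")), tl)
  expect_equal(ip2$mode, "nonpolar")
  ip3 <- initial_polarity(mk(c("nonpolar", "nonpolar", "unipolar_pole1",
                               "unipolar_pole1")), tl)
  expect_equal(ip3$mode, "unipolar")
  expect_equal(ip3$unipolar_pole, 1L)
  # after a division flag, only the frames since the division count
  ip4 <- initial_polarity(mk(c("unipolar_pole2", "excluded_midcell",
                               "nonpolar", "nonpolar")), tl)
  expect_equal(ip4$mode, "nonpolar")
  expect_true(ip4$post_division)
})

test_that("trigger A fires on a sustained new unipolar pole and respects
           the veto", {
  n_f <- length(tl$t_fluor)
  tr <- still_track(tl, y = 30, theta = pi / 2)
  base <- rep("nonpolar", n_f)
  # swap at 45 min: fluor frames 23+ are post-swap (t = 46, 48, ...)
  cls <- base
  cls[c(26, 27)] <- "unipolar_pole2"  # 2 of 4 consecutive frames
  ev <- detect_event(polarity_series(tl, cls), tr, tl)
  expect_equal(ev$trigger, "polarity_first")
  expect_equal(ev$new_leading_pole, 2L)
  expect_equal(ev$fluor_frame, 25L)
  expect_equal(ev$initial_polarity, "nonpolar")
  # the same series is vetoed when pole 2 was already unipolar pre-swap
  cls_veto <- cls
  cls_veto[c(20, 22)] <- "unipolar_pole2"  # 2 of the 4 pre-swap frames
  expect_null(detect_event(polarity_series(tl, cls_veto), tr, tl))
  # ... or unipolar there in the frame immediately preceding the swap
  cls_veto2 <- cls
  cls_veto2[23] <- "unipolar_pole2"
  expect_null(detect_event(polarity_series(tl, cls_veto2), tr, tl))
  # a single isolated unipolar frame is not sustained: no event
  cls_single <- base
  cls_single[26] <- "unipolar_pole2"
  expect_null(detect_event(polarity_series(tl, cls_single), tr, tl))
})

test_that("trigger B fires when a stationary cell moves off at one cell
           width per frame", {
  n_f <- length(tl$t_fluor)
  tr <- still_track(tl, y = 30, theta = pi / 2)
  k <- match(400, tr$frame)
  run <- seq(k + 1, nrow(tr))
  tr$y_um[run] <- tr$y_um[run] + 1.0 * pmin(seq_along(run), 8)
  ev <- detect_event(polarity_series(tl, rep("bipolar", n_f)), tr, tl)
  expect_equal(ev$trigger, "movement_first")
  expect_equal(ev$event_frame, 400)
  # moving towards +y with orientation pi/2: pole 1 (+axis end) leads
  expect_equal(ev$new_leading_pole, 1L)
  # epoch 2 has the high side at low y, so moving up-y is incorrect
  expect_equal(ev$direction_call, "incorrect")
})

test_that("no event is emitted for cells whose polarity never changes", {
  tr <- still_track(tl, y = 30)
  for (cls in c("nonpolar", "unipolar_pole1", "unipolar_pole2", "bipolar")) {
    ev <- detect_event(polarity_series(tl, rep(cls, length(tl$t_fluor))),
                       tr, tl)
    expect_null(ev)
  }
})

test_that("correctness compares pole concentrations under the current
           epoch and mirrors with the field", {
  pose <- data.frame(x_um = 50, y_um = 30, orientation_rad = pi / 2,
                     length_um = 3, width_um = 0.9)
  # epoch 1 (t < 45): sign +1, high concentration at large y; pole 1 is the
  # +y end of the cell
  expect_equal(classify_correctness(1, pose, tl, 10), "correct")
  expect_equal(classify_correctness(2, pose, tl, 10), "incorrect")
  # mirroring the field about the gradient axis (the epoch flip) negates
  # every call
  set.seed(33)
  for (i in 1:20) {
    p <- data.frame(x_um = runif(1, 10, 90), y_um = runif(1, 10, 45),
                    orientation_rad = runif(1, 0.2, pi - 0.2),
                    length_um = runif(1, 1.8, 3.6), width_um = 0.9)
    pole <- sample(1:2, 1)
    c_before <- classify_correctness(pole, p, tl, 10)   # epoch sign +1
    c_after <- classify_correctness(pole, p, tl, 50)    # epoch sign -1
    expect_false(identical(c_before, c_after))
  }
})

test_that("temporal change classifies step-up vs step-down with a
           centreline dead zone", {
  # epoch 1: high side at large y; C(30) < C_max / 2 < C(70)
  low <- data.frame(x_um = 50, y_um = 30)
  high <- data.frame(x_um = 50, y_um = 70)
  centre <- data.frame(x_um = 50, y_um = 50.5)
  expect_equal(assign_temporal_change(low, tl), "step_up")
  expect_equal(assign_temporal_change(high, tl), "step_down")
  expect_equal(assign_temporal_change(centre, tl), "not_assignable")
})

test_that("event summaries reproduce count ratios and test results", {
  ev <- data.frame(direction_call = rep(c("correct", "incorrect"),
                                        c(148, 23)),
                   initial_polarity = "unipolar")
  s <- summarize_events(ev)
  expect_equal(round(s$overall$ratio), 6)
  expect_lt(s$overall$p_value, 1e-10)
  expect_true(s$overall$ci_low > 0.5)
  s0 <- summarize_events(NULL)
  expect_equal(s0$n_events, 0L)
  expect_null(s0$overall)
  ev2 <- data.frame(direction_call = rep(c("correct", "incorrect"), c(10, 2)))
  s2 <- summarize_events(ev2)
  expect_equal(s2$overall$n_correct, 10)
  expect_equal(s2$overall$n_incorrect, 2)
})
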