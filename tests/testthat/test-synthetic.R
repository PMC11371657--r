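# Synthetic generator: trajectories, rendering, experiment assembly and
# its statistical ground-truth guarantees.

base_cfg <- function(...) {
  scenario_config("alternating_gradient", n_cells = 4,
                  field_size = c(256, 256), duration = 10, rng_seed = 5, ...)
}

test_that("a stationary cell with zero jitter never moves", {
  cfg <- base_cfg(stationary_jitter_sd = 0)
  tr <- simulate_twitching_track(cfg, 1, init = list(stationary = TRUE))
  expect_equal(length(unique(tr$x_um)), 1)
  expect_equal(length(unique(tr$y_um)), 1)
})

test_that("uniform motion covers speed times time along the body axis", {
  cfg <- scenario_config("alternating_gradient", n_cells = 1,
                         field_size = c(2048, 2048), duration = 60,
                         mean_speed = 0.2, jump_probability_per_frame = 0,
                         reversal_rate_baseline = 0, rng_seed = 2)
  tr <- simulate_twitching_track(cfg, 3,
                                 init = list(x = 100, y = 100,
                                             orientation = 0.7,
                                             stationary = FALSE))
  net <- c(tr$x_um[nrow(tr)] - tr$x_um[1], tr$y_um[nrow(tr)] - tr$y_um[1])
  # 0.2 um/min for (450 - 1) frames at 7.5 frames/min
  expect_equal(sqrt(sum(net^2)), 0.2 * 449 / 7.5, tolerance = 1e-9)
  u <- c(cos(0.7), sin(0.7))
  expect_equal(abs(sum(net * u)), sqrt(sum(net^2)), tolerance = 1e-9)
})

test_that("reversal counts follow the commanded Poisson rate", {
  cfg <- scenario_config("alternating_gradient", n_cells = 1,
                         field_size = c(4096, 4096), duration = 100,
                         reversal_rate_baseline = 0.01,
                         jump_probability_per_frame = 0,
                         stationary_fraction = 0, rng_seed = 3)
  total <- 0
  for (s in 1:100) {  # 100 cells x 100 min = 1e4 cell-minutes
    tr <- simulate_twitching_track(cfg, 1000 + s,
                                   init = list(x = 200, y = 200,
                                               stationary = FALSE))
    total <- total + sum(tr$is_reversal_true)
  }
  lambda <- 0.01 * 1e4
  expect_lt(abs(total - lambda), 3 * sqrt(lambda))
})

test_that("rendering puts cells, foci and the dye gradient where scripted", {
  cfg <- base_cfg()
  # no cells: background everywhere
  empty <- render_frame(NULL, NULL, NULL, cfg, channels = "cell")$cell
  expect_true(all(empty == cfg$background))
  # one unipolar cell: fluorescence argmax lands at the bright pole
  pose <- one_pose(x = 12, y = 12, theta = 0, len = 3)
  states <- data.frame(amp1 = 0.5, amp2 = 0)
  img <- render_frame(pose, states, NULL, cfg, channels = "fluor")$fluor
  peak <- which(img == max(img), arr.ind = TRUE)[1, ]
  peak_xy <- (c(peak[2], peak[1]) - 0.5) * cfg$pixel_size
  tip <- c(12 + 1.5, 12)  # pole 1 tip; focus sits focus_inset inside it
  expect_lt(sqrt(sum((peak_xy - (tip - c(cfg$focus_inset, 0)))^2)),
            cfg$focus_sigma)
  # dye channel: row means increase monotonically along the gradient axis
  field <- concentration_field(cfg$gradient_params, "alternating_gradient",
                               mid = 12.8)
  dye <- render_frame(NULL, NULL, field, cfg, t = 0, channels = "dye")$dye
  rm_means <- rowMeans(dye)
  expect_true(all(diff(rm_means) >= 0))
  ys <- (seq_len(256) - 0.5) * cfg$pixel_size
  expect_equal(rm_means,
               cfg$dye_gain * field$evaluate(ys, 0) + cfg$dye_offset,
               tolerance = 1e-12)
})

test_that("experiment frame counts follow the two frame rates", {
  cfg <- scenario_config("alternating_gradient", n_cells = 3,
                         field_size = c(256, 256), duration = 60,
                         frame_rate_cell = 7.5, frame_rate_fluor = 0.5,
                         rng_seed = 4)
  sim <- simulate_experiment(cfg)
  expect_length(sim$t_cell, 450)
  expect_length(sim$t_fluor, 30)
  expect_equal(sim$fluor_stride, 15L)
  expect_error(scenario_config(frame_rate_cell = 7.5, frame_rate_fluor = 0.4),
               "integer multiple")
  expect_error(base_cfg(swap_times = 20), "swap_times")
})

test_that("identical config and seed reproduce identical output", {
  cfg <- base_cfg()
  s1 <- simulate_experiment(cfg)
  s2 <- simulate_experiment(cfg)
  expect_identical(s1$ground_truth$poses, s2$ground_truth$poses)
  expect_identical(s1$ground_truth$polarity, s2$ground_truth$polarity)
  f1 <- render_sim_frame(s1, 0, c("cell", "fluor"))
  f2 <- render_sim_frame(s2, 0, c("cell", "fluor"))
  expect_identical(f1, f2)
  # and the written stacks are byte-identical
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_experiment(s1, d1, channels = "fluor")
  write_experiment(s2, d2, channels = "fluor")
  expect_identical(unname(tools::md5sum(file.path(d1, "fluor_channel.tif"))),
                   unname(tools::md5sum(file.path(d2, "fluor_channel.tif"))))
})

test_that("scripted events appear verbatim in the ground truth", {
  spec <- repolarization_spec(cell_id = 1:12, fluor_frame = rep(26:31, 2),
                              correct = rep(c(TRUE, FALSE), c(10, 2)))
  cfg <- scenario_config("alternating_gradient", n_cells = 20,
                         field_size = c(1024, 1024), duration = 90,
                         swap_times = 45, repolarization_spec = spec,
                         rng_seed = 6)
  sim <- simulate_experiment(cfg)
  ev <- sim$ground_truth$events
  expect_equal(nrow(ev), 12)
  expect_equal(sum(ev$direction_call == "correct"), 10)
  expect_equal(sum(ev$direction_call == "incorrect"), 2)
  expect_setequal(ev$cell_id, 1:12)
  expect_equal(ev$fluor_frame[order(ev$cell_id)], rep(26:31, 2))
  # scripted events survive a round trip through the detector when run on
  # the noiseless ground-truth polarity timelines (pipeline closure)
  gt <- sim$ground_truth$polarity
  names(gt)[names(gt) == "class_true"] <- "polarity_class"
  tl <- gradient_timeline(cfg$swap_times, cfg$duration, cfg$frame_rate_cell,
                          cfg$frame_rate_fluor, sim$field)
  det <- find_repolarization_events(gt, sim$ground_truth$poses, tl)
  m <- merge(ev, det, by = "cell_id", suffixes = c("_true", "_det"))
  expect_equal(nrow(m), 12)
  expect_equal(m$fluor_frame_det, m$fluor_frame_true)
  expect_equal(m$direction_call_det, m$direction_call_true)
  expect_equal(nrow(det), 12)
})

test_that("realized speeds and the stationary fraction match the config", {
  cfg <- scenario_config("alternating_gradient", n_cells = 400,
                         field_size = c(4096, 4096), duration = 30,
                         stationary_fraction = 0.075,
                         jump_probability_per_frame = 0, rng_seed = 9)
  sim <- simulate_experiment(cfg)
  poses <- sim$ground_truth$poses
  motile <- poses[!poses$stationary, ]
  sp <- unlist(lapply(split(motile, motile$cell_id), compute_speed))
  expect_gt(length(sp), 1e3)
  expect_equal(mean(sp), cfg$mean_speed, tolerance = 0.05)
  frac <- mean(vapply(split(poses$stationary, poses$cell_id), `[`, TRUE, 1))
  margin <- 1.96 * sqrt(0.075 * 0.925 / 400)
  expect_lt(abs(frac - 0.075), margin + 1e-9)
})
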