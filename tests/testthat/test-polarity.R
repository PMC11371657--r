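# Longitudinal profiling, pole metrics, polarity classification and
# threshold calibration.

cfg_img <- scenario_config("alternating_gradient", n_cells = 1,
                           field_size = c(256, 256), duration = 10,
                           rng_seed = 5)
tcfg <- threshold_config()

test_that("a uniform image gives a flat profile with I1 = I2 = 1", {
  img <- matrix(7, 200, 200)
  prof <- sample_longitudinal_profile(img, one_pose(x = 10, y = 10,
                                                    theta = 0.8), tcfg)
  expect_equal(prof$intensity, rep(7, nrow(prof)))
  m <- pole_metrics(prof, tcfg)
  expect_equal(m$I1, 1)
  expect_equal(m$I2, 1)
})

test_that("a polar focus peaks at the right end of the profile, on or off
           the centreline", {
  pose <- one_pose(x = 12, y = 12, theta = 0.4, len = 3)
  on_states <- data.frame(amp1 = 0.5, amp2 = 0)
  img_on <- render_frame(pose, on_states, NULL, cfg_img,
                         channels = "fluor")$fluor
  prof_on <- sample_longitudinal_profile(img_on, pose, tcfg,
                                         cfg_img$pixel_size)
  s_peak <- prof_on$s[which.max(prof_on$intensity)]
  # focus centre sits focus_inset inside pole 1 (s = inset / length), well
  # inside the pole tenth of the profile
  expect_lt(abs(s_peak - cfg_img$focus_inset / 3), cfg_img$focus_sigma / 3)
  # same focus displaced 0.3 um off the centreline: the 10-line maximum
  # still captures nearly the full peak amplitude
  off_states <- data.frame(amp1 = 0.5, amp2 = 0, off1 = 0.3, off2 = 0)
  img_off <- render_frame(pose, off_states, NULL, cfg_img,
                          channels = "fluor")$fluor
  prof_off <- sample_longitudinal_profile(img_off, pose, tcfg,
                                          cfg_img$pixel_size)
  expect_equal(max(prof_off$intensity), max(prof_on$intensity),
               tolerance = 0.1)
})

test_that("pole metrics normalise pole maxima by the mid-cell mean", {
  s <- seq(0, 1, length.out = 101)
  v <- rep(1, 101); v[3] <- 5  # pole-1 peak of 5x background
  m <- pole_metrics(data.frame(s = s, intensity = v), tcfg)
  expect_equal(m$I1, 5)
  expect_equal(m$I2, 1)
  # zero mid-cell signal invalidates the record
  m0 <- pole_metrics(data.frame(s = s, intensity = c(rep(1, 20),
                                                     rep(0, 61),
                                                     rep(1, 20))), tcfg)
  expect_false(m0$valid)
  expect_equal(classify_polarity(m0, tcfg), "invalid")
})

test_that("scripted pole amplitude ratios are recovered from rendered cells", {
  pose <- one_pose(x = 12, y = 12, theta = 0, len = 3)
  # amplitudes chosen so the analytic normalised intensities are 9 and 3
  states <- data.frame(amp1 = 8 * cfg_img$fluor_body,
                       amp2 = 2 * cfg_img$fluor_body)
  img <- render_frame(pose, states, NULL, cfg_img, channels = "fluor")$fluor
  m <- pole_metrics(sample_longitudinal_profile(img, pose, tcfg,
                                                cfg_img$pixel_size), tcfg)
  expect_equal(m$I1 / m$I2, 3, tolerance = 0.1)
})

test_that("classification applies the threshold, reassignment and mid-cell
           rules in order", {
  mk <- function(I1, I2, mid = 1) {
    list(pole1_max = I1 * mid, pole2_max = I2 * mid, mid_mean = mid,
         I1 = I1, I2 = I2, valid = TRUE)
  }
  c2 <- threshold_config(I_min = 2, ratio_max = 2)
  expect_equal(classify_polarity(mk(3, 1), c2), "unipolar_pole1")
  expect_equal(classify_polarity(mk(1, 3), c2), "unipolar_pole2")
  expect_equal(classify_polarity(mk(3, 3), c2), "bipolar")
  expect_equal(classify_polarity(mk(1.5, 1.5), c2), "nonpolar")
  # strongly asymmetric "bipolar" reassigned to the stronger pole
  expect_equal(classify_polarity(mk(6, 2.2), c2), "unipolar_pole1")
  # mid-cell fluorescence exceeding both poles wins over everything
  midm <- list(pole1_max = 2, pole2_max = 3, mid_mean = 4, I1 = 0.5,
               I2 = 0.75, valid = TRUE)
  expect_equal(classify_polarity(midm, c2), "excluded_midcell")
})

test_that("classification is scale-invariant and symmetric under pole swap", {
  set.seed(13)
  c2 <- threshold_config(I_min = 2, ratio_max = 3)
  for (i in 1:50) {
    I1 <- runif(1, 0.5, 8); I2 <- runif(1, 0.5, 8); mid <- runif(1, 0.5, 2)
    m <- list(pole1_max = I1 * mid, pole2_max = I2 * mid, mid_mean = mid,
              I1 = I1, I2 = I2, valid = TRUE)
    scaled <- lapply(m, function(v) if (is.numeric(v)) v * 37 else v)
    scaled$I1 <- m$I1; scaled$I2 <- m$I2  # ratios are scale-free
    expect_equal(classify_polarity(scaled, c2), classify_polarity(m, c2))
    sw <- list(pole1_max = m$pole2_max, pole2_max = m$pole1_max,
               mid_mean = mid, I1 = I2, I2 = I1, valid = TRUE)
    map <- c(nonpolar = "nonpolar", bipolar = "bipolar",
             unipolar_pole1 = "unipolar_pole2",
             unipolar_pole2 = "unipolar_pole1",
             excluded_midcell = "excluded_midcell")
    expect_equal(classify_polarity(sw, c2),
                 unname(map[classify_polarity(m, c2)]))
  }
})

test_that("threshold calibration splits a bimodal population and falls back
           on unimodal input", {
  set.seed(23)
  # two-component mixture: background poles at I ~ 1, foci at I ~ 5
  n <- 400
  cls <- sample(c("nonpolar", "unipolar_pole1", "unipolar_pole2", "bipolar"),
                n, replace = TRUE)
  I1 <- ifelse(cls %in% c("unipolar_pole1", "bipolar"),
               rnorm(n, 5, 0.4), rnorm(n, 1, 0.12))
  I2 <- ifelse(cls %in% c("unipolar_pole2", "bipolar"),
               rnorm(n, 5, 0.4), rnorm(n, 1, 0.12))
  recs <- data.frame(I1 = I1, I2 = I2)
  cal <- calibrate_thresholds(recs)
  expect_gt(cal$I_min, 1.5)
  expect_lt(cal$I_min, 4)
  # the calibrated thresholds reclassify the population faithfully; the
  # raw pole values are window maxima, so on focus-free cells they sit
  # slightly above the mid-cell mean
  recs$pole1_max <- I1; recs$pole2_max <- I2; recs$mid_mean <- 0.9
  got <- classify_table(recs, cal)
  expect_gte(mean(got == cls), 0.95)
  # an all-nonpolar population cannot be split: defaults with a warning
  flat <- data.frame(I1 = rnorm(200, 1, 0.1), I2 = rnorm(200, 1, 0.1))
  warns <- capture_warnings(cal0 <- calibrate_thresholds(flat))
  expect_match(warns, "unimodal", all = TRUE)
  expect_length(warns, 2)  # both I_min and ratio_max fall back
  expect_equal(cal0$I_min, threshold_config()$I_min)
  expect_error(calibrate_thresholds(data.frame(I1 = 1:10, I2 = 1:10)),
               "at least 100")
})

test_that("scripted polarity class proportions are reproduced by the
           generator within binomial error", {
  scfg <- scenario_config("alternating_gradient", n_cells = 300,
                          field_size = c(2048, 2048), duration = 20,
                          stationary_fraction = 1, rng_seed = 15)
  sim <- simulate_experiment(scfg)
  per_cell <- vapply(split(sim$ground_truth$polarity,
                           sim$ground_truth$polarity$cell_id),
                     function(d) d$class_true[1], "")
  frac_uni <- mean(per_cell %in% c("unipolar_pole1", "unipolar_pole2"))
  margin <- 1.96 * sqrt(0.55 * 0.45 / 300)
  expect_lt(abs(frac_uni - 0.55), margin + 1e-9)
})
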