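# Independent oracles and small builders shared across the suite.

## brute-force minimum-likelihood two-sided binomial p-value
brute_binom_two_sided <- function(k, n, p0) {
  probs <- dbinom(0:n, n, p0)
  sum(probs[probs <= probs[k + 1] * (1 + 1e-7)])
}

brute_binom_greater <- function(k, n, p0) {
  sum(dbinom(k:n, n, p0))
}

## brute-force conditional exact Poisson two-sample p-value: given
## N = n1 + n2, n1 ~ binomial(N, T1 / (T1 + T2)) under equal rates
brute_poisson_two_sample <- function(n1, T1, n2, T2,
                                     alternative = "two.sided") {
  N <- n1 + n2
  r <- T1 / (T1 + T2)
  if (alternative == "greater") return(brute_binom_greater(n1, N, r))
  if (alternative == "less") return(sum(dbinom(0:n1, N, r)))
  brute_binom_two_sided(n1, N, r)
}

## straight constant-velocity track builder
straight_track <- function(n = 20, dt = 1, speed = 0.2, theta = 0,
                           x0 = 10, y0 = 10) {
  t <- (seq_len(n) - 1) * dt
  data.frame(cell_id = 1L, frame = seq_len(n) - 1L, t_min = t,
             x_um = x0 + speed * t * cos(theta),
             y_um = y0 + speed * t * sin(theta),
             orientation_rad = rep(theta %% pi, n),
             length_um = 3, width_um = 0.9)
}

## classify every row of a polarity table with a given threshold config
classify_table <- function(ptab, cfg) {
  vapply(seq_len(nrow(ptab)), function(i) {
    m <- list(pole1_max = ptab$pole1_max[i], pole2_max = ptab$pole2_max[i],
              mid_mean = ptab$mid_mean[i], I1 = ptab$I1[i], I2 = ptab$I2[i],
              valid = is.finite(ptab$I1[i]))
    classify_polarity(m, cfg)
  }, "")
}

## one-cell pose row for rendering / profiling tests
one_pose <- function(x = 12, y = 12, theta = 0, len = 3, width = 0.9) {
  data.frame(x_um = x, y_um = y, orientation_rad = theta, length_um = len,
             width_um = width)
}

## default gradient timeline over a 90 min alternating experiment
demo_timeline <- function(swap = 45, duration = 90, width_scale = 100,
                          mid = 50) {
  design <- gradient_design(C_max = 2, C_min = 0, width_scale = width_scale)
  field <- concentration_field(design, "alternating_gradient",
                               swap_times = swap, mid = mid)
  gradient_timeline(swap, duration, 7.5, 0.5, field)
}

## constant-position trajectory covering a timeline's cell frames
still_track <- function(timeline, x = 50, y = 30, theta = pi / 2,
                        len = 3) {
  n <- length(timeline$t_cell)
  data.frame(cell_id = 1L, frame = seq_len(n) - 1L,
             t_min = timeline$t_cell, x_um = rep(x, n), y_um = rep(y, n),
             orientation_rad = rep(theta, n), length_um = len,
             width_um = 0.9)
}

## polarity series over a timeline's fluorescence frames
polarity_series <- function(timeline, classes) {
  n <- length(timeline$t_fluor)
  stopifnot(length(classes) == n)
  data.frame(cell_id = 1L, fluor_frame = seq_len(n) - 1L,
             polarity_class = classes, stringsAsFactors = FALSE)
}
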