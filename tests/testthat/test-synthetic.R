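# Synthetic gait-signal generator: determinism, morphology, ground truth
# and the hemiplegic asymmetry preset.

test_that("generation is seeded and reproducible, without touching caller RNG", {
  p <- gait_params(n_strides = 5, seed = 101)
  a <- synth_foot(p)
  b <- synth_foot(p)
  expect_identical(a$recording$gyro, b$recording$gyro)
  expect_identical(a$recording$pressure, b$recording$pressure)
  expect_identical(a$truth, b$truth)
  set.seed(1); before <- rnorm(1)
  set.seed(1); invisible(synth_foot(p)); after <- rnorm(1)
  expect_identical(before, after)
  # different seeds differ
  expect_false(identical(synth_foot(gait_params(n_strides = 5, seed = 102))$recording$gyro,
                         a$recording$gyro))
})

test_that("pressure is exactly zero during every planted swing interval (no noise)", {
  foot <- synth_foot(quiet_params(n_strides = 6, seed = 1))
  rec <- foot$recording
  for (k in seq_len(nrow(foot$truth))) {
    swing <- rec$time > foot$truth$to_time[k] & rec$time < foot$truth$next_hs_time[k]
    expect_true(all(rec$pressure[swing] == 0))
  }
  # heel load negative, forefoot load positive within stance
  k <- 3
  early <- rec$time > foot$truth$hs_time[k] &
    rec$time < foot$truth$hs_time[k] + 0.15
  late <- rec$time > foot$truth$to_time[k] - 0.15 &
    rec$time < foot$truth$to_time[k] - 0.02
  expect_lt(min(rec$pressure[early]), -0.5)
  expect_gt(max(rec$pressure[late]), 0.5)
})

test_that("raw-voltage mode sits at half supply when unloaded", {
  foot <- synth_foot(quiet_params(n_strides = 4, seed = 2), raw_voltage = TRUE)
  rec <- foot$recording
  swing <- rec$time > foot$truth$to_time[2] & rec$time < foot$truth$next_hs_time[2]
  expect_true(all(rec$pressure[swing] == 2.5))
  expect_true(all(rec$pressure >= 0 & rec$pressure <= 5))
})

test_that("planted stance fraction matches the parameter and waveforms are bounded", {
  p <- gait_params(n_strides = 6, stance_fraction = 0.62, seed = 3)
  foot <- synth_foot(p)
  expect_true(all(foot$truth$stance_fraction == 0.62))
  bound_gyro <- p$swing_peak_amplitude * (1 + 4 * p$amp_jitter_sd) +
    5 * p$noise_sd_gyro
  expect_true(all(is.finite(foot$recording$gyro)))
  expect_true(all(abs(foot$recording$gyro) <= bound_gyro))
  expect_error(gait_params(stance_fraction = 1.2), class = "gaitdtw_config_error")
  expect_error(gait_params(swing_peak_amplitude = -5), class = "gaitdtw_config_error")
})

test_that("symmetric noiseless walk: feet identical up to the half-cycle offset", {
  walk <- synth_walk(quiet_params(n_strides = 5, seed = 4),
                     asymmetry_preset(severity = 0))
  l <- walk$left; r <- walk$right
  offset <- round(mean(diff(attr(walk, "truth_left")$hs_time)) / 2 * l$rate)
  n <- length(l$gyro)
  expect_equal(r$gyro[(offset + 1):n], l$gyro[1:(n - offset)], tolerance = 1e-12)
  expect_equal(r$pressure[(offset + 1):n], l$pressure[1:(n - offset)],
               tolerance = 1e-12)
})

test_that("full-severity preset prolongs swing, attenuates peak, advances pressure onset", {
  p <- gait_params(n_strides = 6, seed = 5)
  walk <- synth_walk(p, asymmetry_preset(severity = 1, side = "right"))
  tl <- attr(walk, "truth_left"); tr <- attr(walk, "truth_right")
  expect_gt(mean(tr$swing_duration), mean(tl$swing_duration))
  expect_lt(mean(tr$peak_amplitude), mean(tl$peak_amplitude))
  # same stride period on both sides
  expect_equal(tr$next_hs_time - tr$hs_time, tl$next_hs_time - tl$hs_time)
  # affected-side pressure onset precedes the gyro heel-strike trough
  expect_true(all(tr$pressure_onset_time < tr$hs_time))
  expect_true(all(tl$pressure_onset_time == tl$hs_time))
  # detector sees it too: lower max angular velocity on the affected side
  expect_lt(max(lowpass_filter(walk$right)$gyro),
            max(lowpass_filter(walk$left)$gyro))
})

test_that("preset effects are continuous in severity near the symmetric limit", {
  vals <- vapply(c(0, 0.01, 0.05), function(s) {
    w <- synth_walk(quiet_params(n_strides = 4, seed = 6),
                    asymmetry_preset(severity = s, side = "right"))
    mean(attr(w, "truth_right")$swing_duration)
  }, numeric(1))
  expect_lt(abs(vals[2] - vals[1]), abs(vals[3] - vals[1]))
  expect_lt(abs(vals[2] - vals[1]), 0.01)
})

test_that("cohorts are reproducible from their base seed and mutually distinct", {
  p <- gait_params(n_strides = 4)
  c1 <- synth_cohort(4, p, seed = 900)
  c2 <- synth_cohort(4, p, seed = 900)
  expect_identical(lapply(c1, function(w) w$left$gyro),
                   lapply(c2, function(w) w$left$gyro))
  sigs <- lapply(c1, function(w) w$left$gyro)
  expect_equal(length(unique(lapply(sigs, head, 300))), 4)
})
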