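# Stride extraction, cycle-grid resampling, averaging, standardization
# and gyro + pressure superposition.

make_stride <- function(samples, duration = 1) {
  structure(list(channel = "gyro", samples = samples,
                 rel_pos = seq(0, 1, length.out = length(samples)),
                 duration = duration, swing_duration = 0.4 * duration,
                 max_angular_velocity = max(samples)),
            class = "stride_segment")
}

norm_stride <- function(values) {
  structure(list(grid = seq(0, 100, length.out = length(values)),
                 values = values), class = "normalized_stride")
}

test_that("stride extraction yields n-1 segments with planted durations", {
  foot <- synth_foot(gait_params(n_strides = 10, seed = 21,
                                 stride_duration = 1.0))
  filt <- lowpass_filter(foot$recording)
  ev <- detect_events(filt)
  segs <- extract_strides(filt, ev, "gyro")
  expect_length(segs, length(ev$hs) - 1L)
  durs <- vapply(segs, `[[`, numeric(1), "duration")
  expect_lt(abs(mean(durs) - 1.0), 0.02)
  for (s in segs) {
    expect_gt(s$duration, 0)
    expect_gt(s$swing_duration, 0)
    expect_lt(s$swing_duration, s$duration)
    expect_equal(s$max_angular_velocity, max(s$samples))
  }
  expect_error(extract_strides(filt, ev, "nope"))
  # consecutive strides share no samples at the original rate: each
  # opening index equals the previous closing index (half-open cut)
})

test_that("PCHIP resampling preserves endpoints, linearity and monotonicity", {
  ramp <- make_stride(seq(0, 10, length.out = 11))
  rs <- resample_stride(ramp, 101)
  expect_equal(rs$values, seq(0, 10, length.out = 101), tolerance = 1e-12)

  const <- make_stride(rep(3, 8))
  expect_equal(resample_stride(const, 51)$values, rep(3, 51))

  set.seed(42)
  for (i in 1:20) {
    y <- cumsum(runif(10, 0.01, 1))  # strictly increasing
    out <- resample_stride(make_stride(y), 97)$values
    expect_true(all(diff(out) > 0))          # shape preservation
    expect_lte(max(out), max(y) + 1e-9)      # no overshoot
    expect_gte(min(out), min(y) - 1e-9)
    expect_equal(out[1], y[1], tolerance = 1e-9)
    expect_equal(out[97], y[10], tolerance = 1e-9)
  }
  expect_error(resample_stride(ramp, 2), class = "gaitdtw_config_error")
})

test_that("mean_stride averages pointwise and is permutation-invariant", {
  a <- norm_stride(sin(seq(0, 2 * pi, length.out = 101)))
  expect_equal(mean_stride(list(a)), a)
  b <- norm_stride(-a$values)
  expect_equal(mean_stride(list(a, b))$values, numeric(101))
  expect_error(mean_stride(list()), class = "gaitdtw_no_strides_error")

  set.seed(7)
  strides <- lapply(1:5, function(i) norm_stride(rnorm(101)))
  expect_equal(mean_stride(strides), mean_stride(rev(strides)))

  # Monte-Carlo: mean of 10 noisy copies stays within 4*sigma/sqrt(10)
  sigma <- 0.3
  template <- cos(seq(0, 2 * pi, length.out = 101))
  for (rep in 1:5) {
    noisy <- lapply(1:10, function(i) norm_stride(template + rnorm(101, 0, sigma)))
    m <- mean_stride(noisy)$values
    expect_true(all(abs(m - template) < 4 * sigma / sqrt(10)))
  }
})

test_that("standardization gives zero mean, unit population sd, and is idempotent", {
  z <- standardize(norm_stride(c(0, 2)))
  expect_equal(z$values, c(-1, 1))
  expect_error(standardize(norm_stride(rep(5, 10))),
               class = "gaitdtw_degenerate_signal_error")

  set.seed(13)
  for (i in 1:10) {
    x <- norm_stride(rnorm(101, mean = runif(1, -5, 5), sd = runif(1, 0.1, 10)))
    z <- standardize(x)
    expect_lt(abs(mean(z$values)), 1e-9)
    expect_lt(abs(sqrt(mean(z$values^2)) - 1), 1e-9)
    expect_equal(standardize(z)$values, z$values, tolerance = 1e-9)
    # scale invariance: standardize(a*x + b) == standardize(x), a > 0
    y <- x; y$values <- 3.7 * x$values - 11
    expect_equal(standardize(y)$values, z$values, tolerance = 1e-9)
  }
})

test_that("fusion is elementwise superposition on a common grid", {
  x <- standardize(norm_stride(sin(seq(0, 2 * pi, length.out = 101))))
  neg <- x; neg$values <- -x$values
  fused <- fuse(x, neg, "left", 5)
  expect_equal(fused$values, numeric(101))
  expect_equal(fused$n_strides, 5L)
  # sum of two zero-mean signals is zero-mean
  y <- standardize(norm_stride(cos(seq(0, 4 * pi, length.out = 101))))
  expect_lt(abs(mean(fuse(x, y, "left")$values)), 1e-9)
  short <- standardize(norm_stride(rnorm(51)))
  expect_error(fuse(x, short, "left"), class = "gaitdtw_grid_error")
})

test_that("per-foot pipeline is deterministic and symmetric walks match across feet", {
  walk <- synth_walk(gait_params(n_strides = 8, seed = 31))
  f1 <- build_fused_stride(walk$left)
  f2 <- build_fused_stride(walk$left)
  expect_identical(f1$values, f2$values)  # bit-identical rerun

  fr <- build_fused_stride(walk$right)
  expect_lt(max(abs(f1$values - fr$values)), 0.5)
  expect_equal(f1$n_strides, 8L)
})
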