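adult_cfg <- filter_config(t_seg = 10, fs = 25, order = 6L,
                           f_low = 0.80, f_high = 5)
adult_bp <- design_bandpass(adult_cfg, 25)

test_that("bandpass design has half-power cutoffs and is stable", {
  expect_equal(filter_gain(adult_bp, 0.80), sqrt(0.5), tolerance = 0.02)
  expect_equal(filter_gain(adult_bp, 5), sqrt(0.5), tolerance = 0.02)
  expect_equal(filter_gain(adult_bp, sqrt(0.80 * 5)), 1, tolerance = 0.01)
  expect_equal(filter_gain(adult_bp, 0), 0)
  expect_true(all(Mod(polyroot(rev(adult_bp$a))) < 1))
  expect_error(design_bandpass(filter_config(f_low = 1, f_high = 12.6,
                                             fs = 26), fs = 25), "Nyquist")
})

test_that("zero-phase filtering passes in-band and rejects out-of-band", {
  t <- (0:249) / 25
  # constant series: mean removal + DC zero -> all zero
  expect_equal(filter_segment(rep(4.2, 250), adult_bp), rep(0, 250),
               tolerance = 1e-9)
  # in-band 2 Hz unit sinusoid: amplitude preserved over the central half
  x <- sin(2 * pi * 2 * t)
  y <- filter_segment(x, adult_bp)
  mid <- 63:187
  expect_equal(max(abs(y[mid])), 1, tolerance = 0.05)
  expect_lt(max(abs(y[mid] - x[mid])), 0.05)
  # sub-band 0.1 Hz sinusoid emerges attenuated below 5%
  s <- sin(2 * pi * 0.1 * t)
  expect_lt(max(abs(filter_segment(s, adult_bp)[mid])), 0.05)
})

test_that("zero-phase filtering is linear, symmetric and phase-free", {
  set.seed(21)
  x <- rnorm(250)
  expect_equal(filter_segment(3 * x, adult_bp), 3 * filter_segment(x, adult_bp),
               tolerance = 1e-10)
  # time-reversal symmetry away from the edge transients
  fwd <- rev(filter_segment(x, adult_bp))
  bwd <- filter_segment(rev(x), adult_bp)
  expect_lt(max(abs((fwd - bwd)[63:187])), 2e-3)
  # cross-correlation of an in-band sinusoid with its output peaks at lag 0
  t <- (0:249) / 25
  s <- sin(2 * pi * 1.5 * t)
  y <- filter_segment(s, adult_bp)
  lags <- -10:10
  cc <- vapply(lags, function(l) {
    i <- 50:200
    sum(s[i] * y[i + l])
  }, numeric(1))
  expect_equal(lags[which.max(cc)], 0)
  expect_error(zero_phase_filter(adult_bp, rnorm(15)), "too short")
})

test_that("matrix filtering matches the per-column path", {
  set.seed(9)
  X <- matrix(rnorm(250 * 5), 250, 5)
  Y <- filter_segment(X, adult_bp)
  for (j in 1:5)
    expect_equal(Y[, j], filter_segment(X[, j], adult_bp), tolerance = 1e-12)
})

test_that("the periodic Hann taper has the closed-form sums", {
  w <- hann_window(250)
  expect_equal(sum(w), 125)
  expect_equal(sum(w^2), 3 * 250 / 8)
  expect_equal(w[1], 0)
  tapered <- apply_window(rep(1, 250))
  expect_equal(as.numeric(tapered), w)
  expect_equal(attr(tapered, "win_sum"), 125)
})

test_that("sliding segmentation yields floor((L - n)/hop) + 1 windows", {
  expect_equal(length(sliding_segments(250, 250, 1)), 1L)
  expect_equal(length(sliding_segments(260, 250, 1)), 11L)
  expect_equal(sliding_segments(500, 250, 250), c(1L, 251L))
  expect_error(sliding_segments(100, 250, 1), "shorter")
})
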