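test_that("a noiseless pulseless scene is constant at baseline", {
  seq <- generate_scene(scene_config(rows = 20, cols = 24, duration = 1,
                                     pulse_amp = 0, noise_sd = 0,
                                     baseline = 42))
  expect_true(all(seq$frames == 42))
})

test_that("generation is seed-reproducible and leaves the caller's RNG alone", {
  cfg <- scene_config(rows = 16, cols = 20, duration = 1, seed = 99L)
  a <- generate_scene(cfg)
  set.seed(123)
  before <- .Random.seed
  b <- generate_scene(cfg)
  expect_identical(a$frames, b$frames)
  expect_identical(.Random.seed, before)
  c_ <- generate_scene(scene_config(rows = 16, cols = 20, duration = 1,
                                    seed = 100L))
  expect_false(identical(a$frames, c_$frames))
})

test_that("foreground pixel series are exact sinusoids when noiseless", {
  cfg <- scene_config(rows = 40, cols = 48, duration = 2, noise_sd = 0)
  seq <- generate_scene(cfg)
  t <- (seq_len(n_frames(seq)) - 1) / cfg$fs
  s <- seq$frames[20, 24, ] - cfg$baseline  # ellipse center
  fit <- lm(s ~ sin(2 * pi * 1.2 * t) + cos(2 * pi * 1.2 * t) - 1)
  expect_lt(max(abs(resid(fit))), 1e-9)
  amp <- sqrt(sum(coef(fit)^2))
  expect_gt(amp, 0)
  expect_lte(amp, cfg$pulse_amp * (1 + cfg$amp_heterogeneity) + 1e-9)
})

test_that("scene masks have the advertised geometry", {
  cfg <- scene_config(rows = 120, cols = 160, duration = 0.2, noise_sd = 0)
  gt <- scene_ground_truth(cfg, pooling_config(2, 9L, 2L, 2L))
  # silhouette ellipse covers ~20% of the frame
  expect_equal(mean(gt$masks$silhouette), 0.198, tolerance = 0.02)
  # contour mode: a thin ring strictly inside the silhouette
  cfgc <- scene_config(rows = 120, cols = 160, duration = 0.2,
                       modulation_mode = "contour", noise_sd = 0)
  mc <- scene_ground_truth(cfgc, pooling_config(2, 9L, 2L, 2L))$masks
  expect_lt(mean(mc$foreground), 0.25 * mean(gt$masks$silhouette))
  expect_true(!any(mc$foreground & !mc$silhouette))
  # lattice masks: disjoint, and eroded foreground sits inside the bbox ROI
  expect_true(!any(gt$foreground & gt$background))
  expect_true(all(gt$roi_pulse[gt$foreground]))
  expect_true(!any(gt$roi_pulse & gt$roi_bg))
})

test_that("optional scene terms produce their advertised signals", {
  # flicker puts an in-band tone on static background pixels
  cfg <- scene_config(rows = 16, cols = 20, noise_sd = 0,
                      flicker = list(freq = 2, amp = 0.01))
  seq <- generate_scene(cfg)
  s <- seq$frames[2, 2, ]  # background corner
  bp <- design_bandpass(filter_config(), 25)
  sp <- compute_spectrum(apply_window(filter_segment(s, bp)),
                         spectral_config(fs = 25))
  pk <- spectral_peak(sp, spectral_config(fs = 25))
  expect_equal(unname(pk["max_frequency"]), 2, tolerance = 25 / 1024)

  # reflections carry a scaled copy of the pulse
  cfgr <- scene_config(rows = 24, cols = 30, duration = 4, noise_sd = 0,
                       reflection = list(rect = c(2, 6, 24, 29), gain = 0.5))
  sr <- generate_scene(cfgr)$frames[4, 26, ]
  expect_equal(diff(range(sr)) / 2, 0.5 * cfgr$pulse_amp, tolerance = 0.01)

  # AR(1) noise runs and stays at the stationary scale
  cfga <- scene_config(rows = 12, cols = 12, duration = 4, pulse_amp = 0,
                       noise_sd = 0.3, noise_ar = 0.6, seed = 5L)
  sa <- generate_scene(cfga)$frames
  expect_equal(sd(as.vector(sa)), 0.3, tolerance = 0.05)
})
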