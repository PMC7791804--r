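cfg <- spectral_config(1024L, 0.85, 3.98, fs = 25)
nb <- cfg$n_band

test_that("temporal statistics match closed forms", {
  expect_equal(mean_intensity(0:249), 124.5)
  expect_equal(mean_intensity(rep(c(0, 2), 125)), 1)
  expect_equal(temporal_variance(rep(0, 250)), 0)
  expect_equal(temporal_variance(rep(c(-1, 1), 125)), 250 / 249)
  set.seed(2)
  x <- rnorm(250)
  expect_equal(temporal_variance(3 * x), 9 * temporal_variance(x))
  expect_equal(unname(temporal_variance(cbind(x, 2 * x))),
               c(var(x), 4 * var(x)))
})

test_that("band powers follow their definitions and couplings", {
  single <- numeric(nb); single[40] <- 3.5
  expect_equal(spectral_band_powers(spectrum_from_band(single, cfg), cfg),
               c(band_power = 3.5, band_mean_power = 3.5 / nb,
                 band_max_over_band_power = 1))
  flat <- spectral_band_powers(spectrum_from_band(rep(2, nb), cfg), cfg)
  expect_equal(unname(flat), c(2 * nb, 2, 1 / nb))
  zero <- spectral_band_powers(spectrum_from_band(numeric(nb), cfg), cfg)
  expect_equal(unname(zero), c(0, 0, 1 / nb))
})

test_that("spectral moments treat the band as a distribution", {
  f <- cfg$f_band
  single <- numeric(nb); single[10] <- 1
  m <- spectral_moments(spectrum_from_band(single, cfg), cfg)
  expect_equal(unname(m), c(f[10], 0, 0, 0))

  flat <- spectral_moments(spectrum_from_band(rep(1, nb), cfg), cfg)
  expect_equal(unname(flat["spectral_centroid"]), mean(f))
  expect_equal(unname(flat["spectral_skewness"]), 0, tolerance = 1e-10)

  two <- numeric(nb); two[c(5, 105)] <- 1
  m2 <- spectral_moments(spectrum_from_band(two, cfg), cfg)
  expect_equal(unname(m2["spectral_spread"]), (f[105] - f[5]) / 2)
  expect_equal(unname(m2["spectral_kurtosis"]), 1)
})

test_that("shape descriptors hit their analytic extremes", {
  flat <- spectral_shape(spectrum_from_band(rep(3, nb), cfg), cfg)
  expect_equal(unname(flat), c(1, 1, 1, 0), tolerance = 1e-10)

  single <- numeric(nb); single[60] <- 2
  s1 <- spectral_shape(spectrum_from_band(single, cfg), cfg)
  expect_equal(unname(s1[c("spectral_crest", "spectral_flatness",
                           "spectral_entropy")]), c(nb, 0, 0))

  # a noiseless line P = a f + b is recovered exactly by the regression
  f <- cfg$f_band
  lin <- 0.8 * f + 2
  sl <- spectral_shape(spectrum_from_band(lin, cfg), cfg)
  expect_equal(unname(sl["spectral_slope"]), 0.8, tolerance = 1e-10)

  zero <- spectral_shape(spectrum_from_band(numeric(nb), cfg), cfg)
  expect_equal(unname(zero), c(1, 1, 1, 0))
})

test_that("the in-band peak yields frequency and phasor", {
  f0 <- 82 * 25 / 1024  # grid-aligned, ~2.002 Hz
  x <- cos(2 * pi * f0 * (0:249) / 25)
  sp <- compute_spectrum(apply_window(x - mean(x)), cfg)
  pk <- spectral_peak(sp, cfg)
  expect_equal(unname(pk["max_frequency"]), f0, tolerance = 25 / 1024)
  expect_equal(unname(pk["phasor_phase"]), 0, tolerance = 0.05)
  # amplitude scales linearly
  sp3 <- compute_spectrum(apply_window(3 * (x - mean(x))), cfg)
  expect_equal(unname(spectral_peak(sp3, cfg)["phasor_amp"]),
               3 * unname(pk["phasor_amp"]), tolerance = 1e-10)
  # all-zero band: conventions
  z <- spectral_peak(spectrum_from_band(numeric(nb), cfg), cfg)
  expect_equal(unname(z), c(cfg$f_band[1], 0, 0))
})

test_that("spectral fluxes rectify power change and their ratios sum to 1", {
  base <- rep(1, nb)
  spA <- spectrum_from_band(base, cfg)
  expect_equal(unname(spectral_fluxes(spA, spA, cfg)), c(0, 0, 0.5, 0.5))
  bump <- base; bump[7] <- 1 + 0.25
  fx <- spectral_fluxes(spA, spectrum_from_band(bump, cfg), cfg)
  expect_equal(unname(fx), c(0.25, 0, 1, 0))
  for (seed in 1:5) {
    fr <- spectral_fluxes(rand_spectrum(seed), rand_spectrum(seed + 100), cfg)
    expect_equal(unname(fr["ratio_flux_pos"] + fr["ratio_flux_neg"]), 1)
  }
})

test_that("randomized spectra respect the bank's range invariants", {
  for (seed in 1:10) {
    sp <- rand_spectrum(seed)
    bp <- spectral_band_powers(sp, cfg)
    sh <- spectral_shape(sp, cfg)
    mo <- spectral_moments(sp, cfg)
    expect_gte(sh[["spectral_flatness"]], 0)
    expect_lte(sh[["spectral_flatness"]], 1)
    expect_gte(sh[["spectral_entropy"]], 0)
    expect_lte(sh[["spectral_entropy"]], 1)
    expect_gte(sh[["spectral_crest"]], 1)
    expect_lte(sh[["spectral_crest"]], nb)
    expect_gte(mo[["spectral_centroid"]], cfg$f_band_low - 25 / 1024)
    expect_lte(mo[["spectral_centroid"]], cfg$f_band_high + 25 / 1024)
    # exact affine couplings across the bank
    expect_equal(bp[["band_power"]], nb * bp[["band_mean_power"]])
    expect_equal(sh[["spectral_crest"]],
                 nb * bp[["band_max_over_band_power"]])
  }
})

test_that("permutation of in-band bins moves location, not mass features", {
  sp <- rand_spectrum(77)
  set.seed(1)
  perm <- sample(nb)
  band <- (cfg$b_low:cfg$b_high) + 1L
  spp <- sp
  spp$P[band] <- sp$P[band][perm]
  spp$X[band] <- sp$X[band][perm]
  expect_equal(spectral_band_powers(spp, cfg), spectral_band_powers(sp, cfg))
  keep <- c("spectral_crest", "spectral_flatness", "spectral_entropy")
  expect_equal(spectral_shape(spp, cfg)[keep], spectral_shape(sp, cfg)[keep])
  expect_false(isTRUE(all.equal(spectral_moments(spp, cfg)[["spectral_centroid"]],
                                spectral_moments(sp, cfg)[["spectral_centroid"]])))
})

test_that("build_maps lays out all 20 features on the lattice", {
  set.seed(30)
  n_pix <- 12L
  raw <- matrix(runif(250 * n_pix, 90, 110), 250, n_pix)
  bpf <- design_bandpass(filter_config(), 25)
  filt <- filter_segment(raw, bpf)
  w <- hann_window(250)
  sp <- compute_spectra(filt * w, cfg, sum(w))
  fm <- compute_feature_matrix(raw, filt, sp, cfg)
  maps <- build_maps(fm, c(3L, 4L), t0 = 2)
  expect_length(maps, 20L)
  expect_identical(names(maps), feature_ids())
  expect_true(all(vapply(maps, function(m) all(dim(m$values) == c(3, 4)),
                         logical(1))))
  # pixel 5 (row 2, col 2 column-major) lands at its own lattice position
  expect_equal(maps$band_power$values[2, 2], unname(fm[5, "band_power"]))
  expect_equal(maps$mean_intensity$values[1, 1], mean(raw[, 1]))
  fm_bad <- fm; fm_bad[1, 1] <- NA
  expect_error(build_maps(fm_bad, c(3L, 4L)), "missing")
})
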