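# shared fixtures, all generated in code

desk_fs <- 25

# a synthetic segment_spectrum with reproducible random in-band power
rand_spectrum <- function(seed, n_fft = 1024L, fs = 25) {
  set.seed(seed)
  n <- n_fft / 2 + 1L
  amp <- stats::rgamma(n, shape = 1)
  ph <- stats::runif(n, -pi, pi)
  X <- sqrt(amp) * exp(1i * ph)
  structure(list(X = X, P = 2 * Mod(X)^2 / 125^2,
                 freqs = (0:(n_fft / 2)) * fs / n_fft),
            class = "segment_spectrum")
}

# spectrum with prescribed in-band power values (zero elsewhere)
spectrum_from_band <- function(p_band, cfg) {
  n <- cfg$n_fft / 2 + 1L
  P <- numeric(n)
  P[(cfg$b_low:cfg$b_high) + 1L] <- p_band
  X <- complex(modulus = sqrt(P / 2) * 125, argument = 0)
  structure(list(X = X, P = P, freqs = (0:(cfg$n_fft / 2)) * cfg$fs / cfg$n_fft),
            class = "segment_spectrum")
}

# small scene for fast pipeline runs
small_scene <- function(seed = 1L, ...) {
  scene_config(rows = 64L, cols = 80L, seed = seed, ...)
}

# one cached default desk run, shared across tests that only read it
.run_cache <- new.env(parent = emptyenv())
default_run <- function() {
  if (is.null(.run_cache$run))
    .run_cache$run <- run_pipeline(small_scene(seed = 42L), preset = "desk",
                                   similarity_features = "spectral_flatness")
  .run_cache$run
}
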