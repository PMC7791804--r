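#' Spectral analysis configuration
#'
#' Transform length, zero-padding flag and the analysis band resolved to
#' single-sided FFT bins. Band edges map to bins by nearest-bin rounding
#' (`b = round(f * n_fft / fs)`, half away from zero); with `fs = 25` and
#' `n_fft = 1024` the adult band 0.85--3.98 Hz spans 129 bins and the baby
#' band 1.51--3.66 Hz spans 89.
#'
#' @param n_fft transform length in samples (power of two, >= window
#'   length).
#' @param f_band_low,f_band_high analysis band edges in Hz.
#' @param fs sampling rate in Hz.
#' @param zero_pad pad windowed segments to `n_fft` (the reference chain
#'   always does).
#' @return an object of class `spectral_config` with derived `b_low`,
#'   `b_high`, `n_band` and the in-band bin frequencies `f_band`.
#' @export
spectral_config <- function(n_fft = 1024L, f_band_low = 0.85,
                            f_band_high = 3.98, fs = 25, zero_pad = TRUE) {
  stopifnot(n_fft >= 2, bitwAnd(n_fft, n_fft - 1L) == 0L)
  bb <- band_bins(f_band_low, f_band_high, fs, n_fft)
  structure(list(n_fft = as.integer(n_fft), zero_pad = isTRUE(zero_pad),
                 f_band_low = f_band_low, f_band_high = f_band_high, fs = fs,
                 b_low = bb[["b_low"]], b_high = bb[["b_high"]],
                 n_band = bb[["n_band"]],
                 f_band = (bb[["b_low"]]:bb[["b_high"]]) * fs / n_fft),
            class = "spectral_config")
}

#' Resolve band edges to FFT bins
#'
#' Maps each band edge to its nearest single-sided FFT bin,
#' `b = round(f * n_fft / fs)` with halves rounded away from zero. This is
#' the only edge mapping consistent with both reference in-band counts
#' (129 adult, 89 baby); flooring or ceiling both edges gives 128/88.
#'
#' @param f_band_low,f_band_high band edges in Hz,
#'   `0 < f_band_low <= f_band_high < fs/2`.
#' @param fs sampling rate in Hz.
#' @param n_fft transform length.
#' @return named integer vector `c(b_low, b_high, n_band)` (0-based bins).
#' @export
band_bins <- function(f_band_low, f_band_high, fs, n_fft) {
  if (!(0 < f_band_low && f_band_low <= f_band_high && f_band_high < fs / 2))
    stop("band edges must satisfy 0 < low <= high < fs/2", call. = FALSE)
  rnd <- function(x) as.integer(floor(x + 0.5))  # half away from zero, x > 0
  b_low <- rnd(f_band_low * n_fft / fs)
  b_high <- rnd(f_band_high * n_fft / fs)
  if (b_high < b_low) stop("band collapses to zero bins", call. = FALSE)
  c(b_low = b_low, b_high = b_high, n_band = b_high - b_low + 1L)
}

#' Windowed-segment spectrum and scaled power spectrum
#'
#' Zero-pads the windowed segment to `n_fft` samples, takes the DFT, keeps
#' the single-sided half (`n_fft/2 + 1` bins) and scales the power spectrum
#' as `P[k] = 2 |X[k]|^2 / (sum of window values)^2`, so a unit-amplitude
#' sinusoid at a bin frequency yields a spectral peak of `A^2/2 = 0.5`
#' after Hann windowing.
#'
#' @param seg a windowed segment from [apply_window()] (the attached
#'   `win_sum` attribute is required -- the scaling is undefined for
#'   unwindowed input).
#' @param cfg a [spectral_config()].
#' @return an object of class `segment_spectrum`: complex `X`, power `P`,
#'   bin frequencies `freqs` (Hz).
#' @export
compute_spectrum <- function(seg, cfg) {
  win_sum <- attr(seg, "win_sum")
  if (is.null(win_sum))
    stop("segment must be windowed first (apply_window)", call. = FALSE)
  sp <- compute_spectra(matrix(as.numeric(seg), ncol = 1L), cfg, win_sum)
  structure(list(X = sp$X[, 1L], P = sp$P[, 1L], freqs = sp$freqs),
            class = "segment_spectrum")
}

#' Spectra of a full segment lattice
#'
#' Matrix form of [compute_spectrum()]: one windowed pixel series per
#' column. Used by the pipeline to transform all lattice pixels of one
#' segment at once.
#'
#' @param W numeric matrix `n_win x n_pix` of windowed series.
#' @param cfg a [spectral_config()].
#' @param win_sum sum of the window coefficients.
#' @return list with complex matrix `X` and power matrix `P`
#'   (`n_fft/2 + 1` rows) and `freqs`.
#' @export
compute_spectra <- function(W, cfg, win_sum) {
  n <- nrow(W)
  if (n > cfg$n_fft) stop("segment longer than n_fft", call. = FALSE)
  if (cfg$zero_pad && n < cfg$n_fft)
    W <- rbind(W, matrix(0, cfg$n_fft - n, ncol(W)))
  nf <- nrow(W)
  X <- stats::mvfft(W)[seq_len(nf / 2 + 1L), , drop = FALSE]
  list(X = X, P = 2 * Mod(X)^2 / win_sum^2,
       freqs = (0:(nf / 2)) * cfg$fs / nf)
}
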