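#' Temporal filtering configuration
#'
#' Segment length, bandpass design and zero-phase flag for the sliding-window
#' temporal stage. The presets use 10-s segments (250 samples at 25 Hz), an
#' order-6 Butterworth bandpass applied forward-backward (effective order
#' 12), and half-power cutoffs [0.80, 5] Hz (adult) or [1.30, 5] Hz (baby).
#'
#' @param t_seg segment length in seconds.
#' @param fs sampling rate in Hz; `n_seg = round(t_seg * fs)`.
#' @param order design order of the bandpass (even, >= 2). The designed
#'   filter has this order; forward-backward application doubles it
#'   effectively.
#' @param f_low,f_high half-power (-3 dB) cutoff frequencies in Hz,
#'   `0 < f_low < f_high < fs/2`.
#' @param zero_phase apply the filter forward-backward (zero phase
#'   distortion, squared magnitude response).
#' @return an object of class `filter_config`.
#' @export
filter_config <- function(t_seg = 10, fs = 25, order = 6L,
                          f_low = 0.80, f_high = 5, zero_phase = TRUE) {
  stopifnot(t_seg > 0, fs > 0, order >= 2, order %% 2 == 0)
  if (!(0 < f_low && f_low < f_high && f_high < fs / 2))
    stop("cutoffs must satisfy 0 < f_low < f_high < fs/2", call. = FALSE)
  structure(list(t_seg = t_seg, n_seg = as.integer(round(t_seg * fs)),
                 order = as.integer(order), f_low = f_low, f_high = f_high,
                 zero_phase = isTRUE(zero_phase)),
            class = "filter_config")
}

#' Design the recursive bandpass
#'
#' Butterworth bandpass of order `cfg$order` whose single-pass magnitude is
#' -3 dB (1/sqrt(2)) at both cutoffs. Designed via the bilinear transform
#' ([signal::butter()]); stability (all poles strictly inside the unit
#' circle) is asserted.
#'
#' @param cfg a [filter_config()].
#' @param fs sampling rate in Hz.
#' @return a list with numerator `b` and denominator `a`, class `iir_filter`.
#' @export
design_bandpass <- function(cfg, fs) {
  if (cfg$f_high >= fs / 2)
    stop("cutoff at or above Nyquist", call. = FALSE)
  bt <- signal::butter(cfg$order / 2L, c(cfg$f_low, cfg$f_high) / (fs / 2),
                       type = "pass")
  if (any(Mod(polyroot(rev(bt$a))) >= 1))
    stop("designed filter is unstable", call. = FALSE)
  structure(list(b = as.numeric(bt$b), a = as.numeric(bt$a), fs = fs),
            class = "iir_filter")
}

#' Single-pass magnitude response
#'
#' Evaluates `|B(z)/A(z)|` on the unit circle at frequency `f`. The
#' zero-phase (forward-backward) response is this magnitude squared.
#'
#' @param filt an `iir_filter` from [design_bandpass()].
#' @param f frequency (Hz), vectorized.
#' @param fs sampling rate in Hz (defaults to the design rate).
#' @return magnitude gain(s).
#' @export
filter_gain <- function(filt, f, fs = filt$fs) {
  vapply(f, function(fi) {
    z <- exp(-1i * 2 * pi * fi / fs * (seq_along(filt$b) - 1))
    Mod(sum(filt$b * z) / sum(filt$a * z))
  }, numeric(1L))
}

# direct-form II transposed recursion, vectorised over the columns of X;
# zi is the per-unit-step steady state (scaled by the first sample outside)
lfilter_mat <- function(b, a, X, zi = NULL) {
  n <- max(length(a), length(b))
  b <- c(b, rep(0, n - length(b)))
  a <- c(a, rep(0, n - length(a)))
  npix <- ncol(X)
  z <- if (is.null(zi)) matrix(0, n - 1L, npix) else zi
  Y <- matrix(0, nrow(X), npix)
  for (t in seq_len(nrow(X))) {
    xt <- X[t, ]
    yt <- b[1L] * xt + z[1L, ]
    for (i in seq_len(n - 2L))
      z[i, ] <- b[i + 1L] * xt + z[i + 1L, ] - a[i + 1L] * yt
    z[n - 1L, ] <- b[n] * xt - a[n] * yt
    Y[t, ] <- yt
  }
  Y
}

# steady-state initial conditions for unit-step input (direct form II
# transposed): solve (I - A^T) zi = B with the companion matrix of a
lfilter_zi <- function(b, a) {
  n <- max(length(a), length(b))
  b <- c(b, rep(0, n - length(b)))
  a <- c(a, rep(0, n - length(a)))
  comp <- rbind(-a[-1L] / a[1L], cbind(diag(1, n - 2L), 0))
  B <- b[-1L] - a[-1L] * b[1L]
  solve(diag(1, n - 1L) - t(comp), B)
}

#' Zero-phase forward-backward filtering
#'
#' Applies the recursive filter forward and backward so the effective
#' magnitude response is the square of the single pass and phase distortion
#' cancels. Edge transients are controlled by odd-symmetric extension of the
#' series at both ends combined with steady-state initial conditions, which
#' makes the operation symmetric under time reversal. Operates on a vector
#' or on a matrix with one series per column.
#'
#' @param filt an `iir_filter`.
#' @param x numeric vector or matrix (series in columns).
#' @return filtered series, same shape as `x`.
#' @export
zero_phase_filter <- function(filt, x) {
  vec <- is.null(dim(x))
  X <- if (vec) matrix(x, ncol = 1L) else x
  nb <- length(filt$b); na <- length(filt$a)
  pad <- 3L * (max(na, nb) - 1L)
  n <- nrow(X)
  if (n <= pad)
    stop("series too short for reliable zero-phase filtering (need > ",
         pad, " samples)", call. = FALSE)
  top <- 2 * matrix(X[1L, ], pad, ncol(X), byrow = TRUE) -
    X[(pad + 1L):2L, , drop = FALSE]
  bot <- 2 * matrix(X[n, ], pad, ncol(X), byrow = TRUE) -
    X[(n - 1L):(n - pad), , drop = FALSE]
  E <- rbind(top, X, bot)
  zi <- lfilter_zi(filt$b, filt$a)
  Y <- lfilter_mat(filt$b, filt$a, E, zi = outer(zi, E[1L, ]))
  Y <- Y[nrow(Y):1L, , drop = FALSE]
  Y <- lfilter_mat(filt$b, filt$a, Y, zi = outer(zi, Y[1L, ]))
  Y <- Y[nrow(Y):1L, , drop = FALSE]
  Y <- Y[(pad + 1L):(pad + n), , drop = FALSE]
  if (vec) drop(Y) else Y
}

#' Mean-remove and bandpass filter a segment
#'
#' Subtracts the temporal mean of the segment, then applies the bandpass --
#' forward-backward when `zero_phase` (the default), single-pass otherwise.
#'
#' @param series numeric vector of `n_seg` samples, or a matrix with one
#'   pixel series per column.
#' @param filt an `iir_filter` from [design_bandpass()].
#' @param zero_phase logical.
#' @return filtered series, same shape, zero-mean input guaranteed.
#' @export
filter_segment <- function(series, filt, zero_phase = TRUE) {
  vec <- is.null(dim(series))
  X <- if (vec) matrix(series, ncol = 1L) else series
  X <- sweep(X, 2L, colMeans(X))
  Y <- if (zero_phase) zero_phase_filter(filt, X)
       else lfilter_mat(filt$b, filt$a, X)
  if (vec) drop(Y) else Y
}

#' Periodic Hann taper
#'
#' `w[n] = 0.5 - 0.5 cos(2 pi n / N)`, `n = 0..N-1` (periodic form, suited
#' to short-time Fourier analysis). Its coefficient sum `N/2` enters the
#' power-spectrum scaling; the sum of squares is `3N/8`.
#'
#' @param n window length in samples.
#' @return numeric vector of length `n`.
#' @export
hann_window <- function(n) 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1L) / n)

#' Apply the analysis window
#'
#' Pointwise product with the periodic Hann taper. The window's coefficient
#' sum is attached as attribute `win_sum` (needed downstream for the
#' power-spectrum scaling) together with `window = "hann"`.
#'
#' @param seg numeric vector or matrix (series in columns) of length
#'   `n_win`.
#' @param window taper type; only `"hann"` is defined.
#' @return windowed series with attributes `window` and `win_sum`.
#' @export
apply_window <- function(seg, window = "hann") {
  window <- match.arg(window, "hann")
  n <- if (is.null(dim(seg))) length(seg) else nrow(seg)
  w <- hann_window(n)
  out <- if (is.null(dim(seg))) seg * w else seg * w
  structure(out, window = window, win_sum = sum(w))
}

#' Sliding-segment start indices
#'
#' Start positions of consecutive analysis segments of `n_seg` samples
#' advanced by `hop` samples (`hop = n_win - n_overlap`; the reference
#' parametrization uses overlap 249, i.e. hop 1). The number of segments is
#' `floor((L - n_seg) / hop) + 1`.
#'
#' @param n_total total series length in samples.
#' @param n_seg segment length in samples.
#' @param hop hop size in samples, >= 1.
#' @return integer vector of 1-based start indices.
#' @export
sliding_segments <- function(n_total, n_seg, hop = 1L) {
  stopifnot(hop >= 1)
  if (n_total < n_seg)
    stop("series shorter than one segment", call. = FALSE)
  seq.int(1L, n_total - n_seg + 1L, by = hop)
}
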