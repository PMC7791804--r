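#' Spatial pooling configuration
#'
#' Parameters of the ROI-generation stage: a normalized 2-D Gaussian pooling
#' kernel applied as a valid (no-padding) convolution, followed by decimation
#' to the ROI lattice. The chain presets carry sigma 10 / kernel 41 /
#' decimation 5 for the PPGI cameras and sigma 5 / kernel 33 / decimation 1
#' for the thermal camera.
#'
#' @param sigma_gauss Gaussian standard deviation in pixels, > 0.
#' @param n_kernel odd kernel side length in pixels.
#' @param d_x,d_y decimation factors (columns, rows), >= 1.
#' @param b_center if `TRUE`, the decimation grid is anchored at patch
#'   centers: the first kept index is offset by `floor((d - 1) / 2)`.
#' @return an object of class `pooling_config`.
#' @export
pooling_config <- function(sigma_gauss, n_kernel, d_x = 1L, d_y = 1L,
                           b_center = TRUE) {
  stopifnot(sigma_gauss > 0, n_kernel >= 1, n_kernel %% 2 == 1,
            d_x >= 1, d_y >= 1)
  structure(list(sigma_gauss = sigma_gauss, n_kernel = as.integer(n_kernel),
                 d_x = as.integer(d_x), d_y = as.integer(d_y),
                 b_center = isTRUE(b_center)),
            class = "pooling_config")
}

#' Sampled Gaussian pooling kernel
#'
#' Outer product of 1-D Gaussians sampled at integer offsets and
#' renormalized to unit sum, so pooling preserves constant regions.
#'
#' @param sigma standard deviation in pixels.
#' @param n odd side length.
#' @return `n x n` matrix summing to 1.
#' @export
gaussian_kernel <- function(sigma, n) {
  stopifnot(n %% 2 == 1)
  g <- stats::dnorm(seq_len(n) - (n + 1) / 2, sd = sigma)
  g <- g / sum(g)
  outer(g, g)
}

#' Gaussian spatial pooling of one frame
#'
#' Valid convolution with the normalized Gaussian kernel: the output has
#' dimensions `(rows - n_kernel + 1) x (cols - n_kernel + 1)` and every
#' output pixel is a Gaussian-weighted average of its `n_kernel`-sided
#' neighborhood. Implemented separably (row pass then column pass).
#'
#' @param frame 2-D numeric matrix, at least `n_kernel` in both dimensions.
#' @param cfg a [pooling_config()].
#' @return pooled matrix.
#' @export
gaussian_pool <- function(frame, cfg) {
  n <- cfg$n_kernel
  if (nrow(frame) < n || ncol(frame) < n)
    stop("frame smaller than pooling kernel", call. = FALSE)
  g <- stats::dnorm(seq_len(n) - (n + 1) / 2, sd = cfg$sigma_gauss)
  g <- g / sum(g)
  conv_valid_cols(conv_valid_rows(frame, g), g)
}

# valid 1-D convolution down the rows (shift-accumulate, vectorised)
conv_valid_rows <- function(x, g) {
  n <- length(g)
  m <- nrow(x) - n + 1L
  acc <- matrix(0, m, ncol(x))
  for (k in seq_len(n)) acc <- acc + g[k] * x[k:(k + m - 1L), , drop = FALSE]
  acc
}

conv_valid_cols <- function(x, g) {
  n <- length(g)
  m <- ncol(x) - n + 1L
  acc <- matrix(0, nrow(x), m)
  for (k in seq_len(n)) acc <- acc + g[k] * x[, k:(k + m - 1L), drop = FALSE]
  acc
}

#' Decimate a pooled frame to the ROI lattice
#'
#' Keeps every `d_y`-th row and `d_x`-th column. With `b_center` the first
#' kept index is the patch-center offset `floor((d - 1) / 2)`, so lattice
#' pixels sit at the centers of the decimation cells. The output has
#' `floor(rows / d_y) x floor(cols / d_x)` pixels.
#'
#' @param frame 2-D numeric matrix (typically a pooled frame).
#' @param cfg a [pooling_config()].
#' @return decimated matrix.
#' @export
decimate <- function(frame, cfg) {
  frame[decimation_index(nrow(frame), cfg$d_y, cfg$b_center),
        decimation_index(ncol(frame), cfg$d_x, cfg$b_center), drop = FALSE]
}

decimation_index <- function(n, d, center) {
  m <- n %/% d
  off <- if (center) (d - 1L) %/% 2L else 0L
  off + 1L + (seq_len(m) - 1L) * d
}

#' ROI-lattice dimensions for a frame size
#'
#' Resolution arithmetic of the ROI stage:
#' `floor((D - n_kernel + 1) / d)` per axis (valid convolution then
#' decimation). For a 1920x1200 frame with kernel 41 and decimation 5 this
#' gives a 232x376 (rows x cols) lattice; for 640x480 with kernel 33 and
#' decimation 1, 448x608.
#'
#' @param rows,cols frame dimensions in pixels.
#' @param cfg a [pooling_config()].
#' @return integer vector `c(rows, cols)` of the lattice.
#' @export
lattice_dims <- function(rows, cols, cfg) {
  c(rows = (rows - cfg$n_kernel + 1L) %/% cfg$d_y,
    cols = (cols - cfg$n_kernel + 1L) %/% cfg$d_x)
}

#' Pool and decimate every frame of a sequence
#'
#' Applies [gaussian_pool()] and [decimate()] frame by frame, producing the
#' ROI-lattice video whose pixel series feed the temporal stage.
#'
#' @param seq a [frame_sequence()].
#' @param cfg a [pooling_config()].
#' @return a [frame_sequence()] on the ROI lattice.
#' @export
pool_sequence <- function(seq, cfg) {
  n <- n_frames(seq)
  first <- decimate(gaussian_pool(seq$frames[, , 1L], cfg), cfg)
  out <- array(NA_real_, dim = c(dim(first), n))
  out[, , 1L] <- first
  if (n > 1L)
    for (k in 2L:n)
      out[, , k] <- decimate(gaussian_pool(seq$frames[, , k], cfg), cfg)
  frame_sequence(out, fs = seq$fs, bit_depth = seq$bit_depth,
                 modality = seq$modality)
}
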