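#' Similarity measurement configuration
#'
#' Histogram bin count, odd patch side length and boundary padding mode for
#' the histogram-intersection similarity maps (256 bins, 31x31 patches and
#' symmetric padding in the reference chain).
#'
#' @param n_bins histogram bins (must equal the quantization level count).
#' @param n_kernel_hist odd patch side length in lattice pixels.
#' @param padding boundary mode; only `"symmetric"` (mirror reflection
#'   including the edge pixel) is defined.
#' @return an object of class `similarity_config`.
#' @export
similarity_config <- function(n_bins = 256L, n_kernel_hist = 31L,
                              padding = "symmetric") {
  stopifnot(n_bins >= 2, n_kernel_hist >= 1, n_kernel_hist %% 2 == 1)
  padding <- match.arg(padding, "symmetric")
  structure(list(n_bins = as.integer(n_bins),
                 n_kernel_hist = as.integer(n_kernel_hist), padding = padding),
            class = "similarity_config")
}

#' Background model histogram
#'
#' Normalized histogram of the quantized levels inside a reference region
#' (ideally a large, representative background region): bin `j` holds the
#' fraction of region pixels at level `j - 1`.
#'
#' @param qmap integer map of quantization levels in `[0, n_bins - 1]`
#'   ([quantize_map()] output or bare integer matrix).
#' @param region a [region_spec()]; must be non-empty and inside the map.
#' @param n_bins histogram bin count.
#' @return numeric vector of `n_bins` masses summing to 1.
#' @export
model_histogram <- function(qmap, region, n_bins = 256L) {
  v <- if (is.matrix(qmap)) qmap else qmap$values
  if (!all(dim(region$mask) == dim(v)))
    stop("region mask does not match map dimensions", call. = FALSE)
  levels <- v[region$mask]
  if (length(levels) == 0L) stop("empty region", call. = FALSE)
  if (any(levels < 0 | levels >= n_bins))
    stop("levels outside [0, n_bins - 1]", call. = FALSE)
  tabulate(levels + 1L, nbins = n_bins) / length(levels)
}

#' Histogram intersection
#'
#' `eta(H_M, H_P) = sum_j min(H_Mj, H_Pj)` for two normalized histograms of
#' equal length; ranges over `[0, 1]`, equals 1 for identical histograms
#' and 0 for disjoint supports. For normalized histograms
#' `eta = 1 - total-variation distance`.
#'
#' @param h_m,h_p numeric vectors of equal length, each summing to 1.
#' @return similarity in `[0, 1]`.
#' @export
histogram_intersection <- function(h_m, h_p) {
  if (length(h_m) != length(h_p))
    stop("histograms must have the same number of bins", call. = FALSE)
  sum(pmin(h_m, h_p))
}

# symmetric (mirror, edge included) padding index for length n and radius r
symmetric_index <- function(n, r) {
  idx <- c(r:1, 1:n, n:(n - r + 1L))
  if (r == 0L) idx <- 1:n
  idx
}

#' Histogram-intersection similarity map
#'
#' For every lattice pixel, the normalized histogram of the
#' `n_kernel_hist x n_kernel_hist` patch centered on it (boundaries handled
#' by symmetric reflection) is intersected with the background model
#' histogram. Background-like patches score near 1, pulsatile foreground
#' patches near 0. Naive per-pixel computation is the reference semantics.
#'
#' @param qmap integer map of quantization levels ([quantize_map()] output
#'   or bare integer matrix).
#' @param h_model model histogram from [model_histogram()].
#' @param cfg a [similarity_config()].
#' @return a [feature_map()] with `feature_id = "similarity"` and values in
#'   `[0, 1]`.
#' @export
similarity_map <- function(qmap, h_model, cfg = similarity_config()) {
  v <- if (is.matrix(qmap)) qmap else qmap$values
  k <- cfg$n_kernel_hist
  r <- (k - 1L) %/% 2L
  if (r >= min(dim(v)))  # symmetric padding needs radius < map extent
    stop("patch larger than map", call. = FALSE)
  pad <- v[symmetric_index(nrow(v), r), symmetric_index(ncol(v), r)]
  nb <- length(h_model)
  out <- matrix(NA_real_, nrow(v), ncol(v))
  np <- k * k
  for (j in seq_len(ncol(v))) {
    cols <- j:(j + k - 1L)
    for (i in seq_len(nrow(v))) {
      patch <- pad[i:(i + k - 1L), cols]
      hp <- tabulate(patch + 1L, nbins = nb) / np
      out[i, j] <- sum(pmin(h_model, hp))
    }
  }
  t0 <- if (is.matrix(qmap)) 0 else qmap$t0
  feature_map(out, "similarity", t0 = t0)
}
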