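#' Visualization / scaling configuration
#'
#' Parameters of the map postprocessing: decibel factor, zero stabilizer,
#' optional manual display limits, and the quantization level count used to
#' make maps comparable (256 in the reference chain).
#'
#' @param u decibel factor, 10 for power-like or 20 for amplitude-like
#'   quantities.
#' @param epsilon small positive stabilizer guarding `log10` at zero pixels.
#' @param display_limits optional numeric `c(lo, hi)`, `lo < hi`, for the
#'   manual display window.
#' @param n_scale quantization levels, >= 2.
#' @return an object of class `visualization_config`.
#' @export
visualization_config <- function(u = 10, epsilon = 1e-12,
                                 display_limits = NULL, n_scale = 256L) {
  stopifnot(u %in% c(10, 20), epsilon > 0, n_scale >= 2)
  if (!is.null(display_limits))
    stopifnot(length(display_limits) == 2L,
              display_limits[1L] < display_limits[2L])
  structure(list(u = u, epsilon = epsilon, display_limits = display_limits,
                 n_scale = as.integer(n_scale)),
            class = "visualization_config")
}

#' Decibel conversion of a map
#'
#' Elementwise `V(I) = U * log10(|I| + epsilon)`; the stabilizer keeps
#' zero-valued pixels finite. Monotone on nonnegative maps.
#'
#' @param map a [feature_map()] (or bare matrix).
#' @param u decibel factor: 10 for power-like maps (band powers, temporal
#'   variance, fluxes), 20 for amplitude-like maps (phasor amplitude).
#' @param epsilon positive stabilizer.
#' @return the map in dB with `db_scaled` set.
#' @export
db_convert <- function(map, u = 10, epsilon = 1e-12) {
  stopifnot(u %in% c(10, 20), epsilon > 0)
  if (is.matrix(map)) return(u * log10(abs(map) + epsilon))
  feature_map(u * log10(abs(map$values) + epsilon), map$feature_id,
              t0 = map$t0, db_scaled = TRUE)
}

#' Decibel factor per feature
#'
#' Which maps receive the decibel conversion, and with which factor:
#' power-like quantities (band power, band mean power, temporal variance,
#' spectral fluxes) use `U = 10`; the amplitude-like phasor amplitude uses
#' `U = 20`; bounded or ratio-valued maps (flatness, entropy, moments, flux
#' ratios, frequencies, phase, mean intensity) are displayed without
#' conversion (`NA`).
#'
#' @param feature_id a feature identifier from [feature_ids()].
#' @return 10, 20 or `NA`.
#' @export
db_factor_for <- function(feature_id) {
  if (feature_id %in% c("band_power", "band_mean_power", "temporal_var",
                        "spectral_flux_pos", "spectral_flux_neg")) return(10)
  if (feature_id == "phasor_amp") return(20)
  NA_real_
}

#' Normalize a map to [0, 1]
#'
#' `(x - min) / (max - min)` over all pixels of the map -- the scaling used
#' to make maps comparable before quantization and evaluation. A constant
#' map normalizes to all zeros (documented convention); any positive affine
#' transform of the input yields the identical normalized map.
#'
#' @param map a [feature_map()] or bare matrix with finite entries.
#' @return normalized map in `[0, 1]`.
#' @export
normalize_map <- function(map) {
  v <- if (is.matrix(map)) map else map$values
  if (any(!is.finite(v))) stop("map contains non-finite pixels", call. = FALSE)
  rng <- range(v)
  out <- if (rng[1L] == rng[2L]) array(0, dim(v))
         else (v - rng[1L]) / (rng[2L] - rng[1L])
  if (is.matrix(map)) out
  else feature_map(out, map$feature_id, t0 = map$t0, db_scaled = map$db_scaled)
}

#' Quantize a normalized map
#'
#' `level = min(floor(x * n_scale), n_scale - 1)`, integers in
#' `[0, n_scale - 1]`. Input must already be normalized to `[0, 1]`.
#'
#' @param map a normalized [feature_map()] or matrix.
#' @param n_scale number of levels (256 in the reference chain).
#' @return integer map of quantization levels.
#' @export
quantize_map <- function(map, n_scale = 256L) {
  v <- if (is.matrix(map)) map else map$values
  if (any(v < 0 | v > 1)) stop("map must be normalized to [0, 1]", call. = FALSE)
  q <- pmin(floor(v * n_scale), n_scale - 1L)
  storage.mode(q) <- "integer"
  if (is.matrix(map)) q
  else feature_map(q, map$feature_id, t0 = map$t0, db_scaled = map$db_scaled)
}

#' Render a display image with manual window limits
#'
#' Linear gray-scale transform mapping `[lo, hi]` to 8-bit `[0, 255]`
#' (rounded as `floor(x + 0.5)`, so the window midpoint maps to 128);
#' values outside the window are clipped to its ends. Limits are manual by
#' design -- the display path never auto-fits.
#'
#' @param map a [feature_map()] or matrix.
#' @param limits numeric `c(lo, hi)`, `lo < hi`.
#' @return integer matrix of 8-bit gray values.
#' @export
display_window <- function(map, limits) {
  stopifnot(length(limits) == 2L, limits[1L] < limits[2L])
  v <- if (is.matrix(map)) map else map$values
  x <- (v - limits[1L]) / (limits[2L] - limits[1L])
  x <- pmin(pmax(x, 0), 1)
  g <- floor(x * 255 + 0.5)
  storage.mode(g) <- "integer"
  g
}
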