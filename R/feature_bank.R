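#' The feature bank
#'
#' Identifiers of the 20 per-pixel maps computed for every segment: 19
#' dynamic features plus the mean-intensity visual reference, in the bank's
#' canonical order.
#'
#' @return character vector of length 20.
#' @export
feature_ids <- function() {
  c("mean_intensity",
    "band_power", "band_mean_power", "band_max_over_band_power",
    "spectral_centroid", "spectral_spread", "spectral_skewness",
    "spectral_kurtosis", "spectral_crest", "spectral_flatness",
    "spectral_entropy", "spectral_slope",
    "max_frequency", "phasor_phase", "phasor_amp",
    "temporal_var",
    "spectral_flux_pos", "spectral_flux_neg",
    "ratio_flux_pos", "ratio_flux_neg")
}

# in-band power block (n_band x npix) of a power-spectrum matrix (0-based bins)
band_block <- function(P, cfg) P[(cfg$b_low:cfg$b_high) + 1L, , drop = FALSE]

#' Mean intensity of the raw pixel series
#'
#' The temporal mean that is subtracted before filtering; kept as the
#' visual-reference map of the bank.
#'
#' @param series raw (unfiltered) numeric vector, or matrix with one pixel
#'   series per column.
#' @return scalar or per-column vector.
#' @export
mean_intensity <- function(series) {
  if (is.null(dim(series))) mean(series) else colMeans(series)
}

#' Temporal variance of a filtered segment
#'
#' Unbiased sample variance (divisor `n - 1`) of the mean-removed, bandpass
#' filtered, pre-window pixel series -- the bank's only dynamic temporal
#' feature.
#'
#' @param seg filtered numeric vector or matrix (series in columns).
#' @return scalar or per-column vector.
#' @export
temporal_variance <- function(seg) {
  if (is.null(dim(seg))) return(stats::var(seg))
  n <- nrow(seg)
  (colSums(seg^2) - n * colMeans(seg)^2) / (n - 1)
}

#' In-band power summaries
#'
#' `band_power` is the sum of the scaled power spectrum over the analysis
#' band, `band_mean_power` that sum divided by the in-band bin count, and
#' `band_max_over_band_power` the in-band maximum divided by the sum. The
#' all-zero band uses the flat convention: powers 0, ratio `1/n_band`.
#'
#' @param sp a `segment_spectrum` from [compute_spectrum()].
#' @param cfg a [spectral_config()].
#' @return named numeric vector
#'   `(band_power, band_mean_power, band_max_over_band_power)`.
#' @export
spectral_band_powers <- function(sp, cfg) {
  v <- band_powers_mat(band_block(as.matrix(sp$P), cfg), cfg$n_band)
  c(band_power = v$band_power, band_mean_power = v$band_mean_power,
    band_max_over_band_power = v$band_max_over_band_power)
}

band_powers_mat <- function(Pb, n_band) {
  S <- colSums(Pb)
  mx <- apply(Pb, 2L, max)
  list(band_power = S, band_mean_power = S / n_band,
       band_max_over_band_power = ifelse(S > 0, mx / S, 1 / n_band))
}

#' Spectral moments of the in-band distribution
#'
#' The in-band power spectrum, normalized to unit mass `p_k`, is treated as
#' a distribution over the bin frequencies: centroid `sum f_k p_k` (Hz),
#' spread (its standard deviation, Hz), and standardized skewness and
#' kurtosis. Zero spread yields skewness and kurtosis 0 by convention; an
#' all-zero band falls back to the uniform (noise-like) distribution.
#'
#' @inheritParams spectral_band_powers
#' @return named numeric vector `(spectral_centroid, spectral_spread,
#'   spectral_skewness, spectral_kurtosis)`.
#' @export
spectral_moments <- function(sp, cfg) {
  v <- moments_mat(band_prob(band_block(as.matrix(sp$P), cfg)), cfg$f_band)
  c(spectral_centroid = v$centroid, spectral_spread = v$spread,
    spectral_skewness = v$skewness, spectral_kurtosis = v$kurtosis)
}

# normalize in-band power to unit mass per column; all-zero -> uniform
band_prob <- function(Pb) {
  S <- colSums(Pb)
  zero <- S <= 0
  p <- sweep(Pb, 2L, ifelse(zero, 1, S), "/")
  if (any(zero)) p[, zero] <- 1 / nrow(Pb)
  p
}

moments_mat <- function(p, f) {
  centroid <- colSums(p * f)
  dev <- outer(f, centroid, "-")  # wasteful for huge lattices but clear
  m2 <- colSums(p * dev^2)
  m3 <- colSums(p * dev^3)
  m4 <- colSums(p * dev^4)
  spread <- sqrt(m2)
  ok <- spread > 0
  list(centroid = centroid, spread = spread,
       skewness = ifelse(ok, m3 / spread^3, 0),
       kurtosis = ifelse(ok, m4 / spread^4, 0))
}

#' Spectral shape descriptors
#'
#' Crest factor (in-band maximum over mean), flatness (geometric over
#' arithmetic mean; 0 whenever any in-band bin is zero, 1 for the all-zero
#' band), entropy (`-sum p log2 p / log2 n_band`, normalized to `[0, 1]`;
#' 1 for the all-zero band) and slope (least-squares slope of the in-band
#' power regressed on frequency, power/Hz).
#'
#' @inheritParams spectral_band_powers
#' @return named numeric vector `(spectral_crest, spectral_flatness,
#'   spectral_entropy, spectral_slope)`.
#' @export
spectral_shape <- function(sp, cfg) {
  v <- shape_mat(band_block(as.matrix(sp$P), cfg), cfg$f_band)
  c(spectral_crest = v$crest, spectral_flatness = v$flatness,
    spectral_entropy = v$entropy, spectral_slope = v$slope)
}

shape_mat <- function(Pb, f) {
  n <- nrow(Pb)
  S <- colSums(Pb)
  zero <- S <= 0
  mn <- S / n
  mx <- apply(Pb, 2L, max)
  crest <- ifelse(zero, 1, mx / ifelse(zero, 1, mn))
  haszero <- apply(Pb <= 0, 2L, any)
  lg <- log(Pb)
  lg[Pb <= 0] <- 0  # masked below
  gm <- exp(colMeans(lg))
  flat <- ifelse(haszero, 0, gm / ifelse(zero, 1, mn))
  flat[zero] <- 1
  p <- band_prob(Pb)
  pl <- p * log2(p)
  pl[p <= 0] <- 0
  ent <- -colSums(pl) / log2(n)
  ent[zero] <- 1
  fc <- f - mean(f)
  slope <- colSums(fc * Pb) / sum(fc^2)
  list(crest = crest, flatness = flat, entropy = ent, slope = slope)
}

#' In-band peak frequency and phasor
#'
#' The in-band power maximum locates the dominant bin `k*` (ties broken
#' toward the lowest bin): `max_frequency` is its bin frequency,
#' `phasor_amp` the magnitude and `phasor_phase` the argument (in
#' `(-pi, pi]`) of the complex spectrum there. The all-zero band yields the
#' low band edge, amplitude 0 and phase 0.
#'
#' @inheritParams spectral_band_powers
#' @return named numeric vector `(max_frequency, phasor_amp, phasor_phase)`.
#' @export
spectral_peak <- function(sp, cfg) {
  v <- peak_mat(band_block(as.matrix(sp$P), cfg),
                band_block(as.matrix(sp$X), cfg), cfg$f_band)
  c(max_frequency = v$max_frequency, phasor_amp = v$phasor_amp,
    phasor_phase = v$phasor_phase)
}

peak_mat <- function(Pb, Xb, f) {
  kstar <- max.col(t(Pb), ties.method = "first")
  S <- colSums(Pb)
  zero <- S <= 0
  kstar[zero] <- 1L
  xs <- Xb[cbind(kstar, seq_len(ncol(Xb)))]
  amp <- Mod(xs)
  ph <- Arg(xs)
  amp[zero] <- 0
  ph[zero] <- 0
  list(max_frequency = f[kstar], phasor_amp = amp, phasor_phase = ph)
}

#' Spectral flux between consecutive segments
#'
#' Half-wave rectified bin-wise in-band power change between the previous
#' and current segment of the same pixel: `flux_pos` sums increases,
#' `flux_neg` decreases, and the two ratios normalize them to unit sum.
#' When nothing changes (total flux 0) both ratios are 0.5.
#'
#' @param sp_prev,sp_curr `segment_spectrum` objects from consecutive
#'   segment starts of one pixel.
#' @param cfg a [spectral_config()].
#' @return named numeric vector `(spectral_flux_pos, spectral_flux_neg,
#'   ratio_flux_pos, ratio_flux_neg)`.
#' @export
spectral_fluxes <- function(sp_prev, sp_curr, cfg) {
  v <- flux_mat(band_block(as.matrix(sp_prev$P), cfg),
                band_block(as.matrix(sp_curr$P), cfg))
  c(spectral_flux_pos = v$flux_pos, spectral_flux_neg = v$flux_neg,
    ratio_flux_pos = v$ratio_flux_pos, ratio_flux_neg = v$ratio_flux_neg)
}

flux_mat <- function(Pb_prev, Pb_curr) {
  D <- Pb_curr - Pb_prev
  pos <- colSums(pmax(D, 0))
  neg <- colSums(pmax(-D, 0))
  tot <- pos + neg
  rp <- ifelse(tot > 0, pos / tot, 0.5)
  list(flux_pos = pos, flux_neg = neg,
       ratio_flux_pos = rp, ratio_flux_neg = 1 - rp)
}

#' Per-pixel features of one segment lattice
#'
#' Computes all 20 features for every lattice pixel of one segment. Flux
#' features compare against the previous segment's spectra; for the first
#' segment of a run (no predecessor) the no-change convention applies
#' (fluxes 0, ratios 0.5).
#'
#' @param raw raw pixel-series matrix (`n_seg x n_pix`).
#' @param filt filtered (pre-window) matrix, same shape.
#' @param sp spectra of the current segment from [compute_spectra()].
#' @param cfg a [spectral_config()].
#' @param sp_prev spectra of the previous segment start, or `NULL`.
#' @return numeric matrix `n_pix x 20`, columns named by [feature_ids()].
#' @export
compute_feature_matrix <- function(raw, filt, sp, cfg, sp_prev = NULL) {
  Pb <- band_block(sp$P, cfg)
  Xb <- band_block(sp$X, cfg)
  f <- cfg$f_band
  bp <- band_powers_mat(Pb, cfg$n_band)
  mo <- moments_mat(band_prob(Pb), f)
  sh <- shape_mat(Pb, f)
  pk <- peak_mat(Pb, Xb, f)
  fl <- if (is.null(sp_prev)) flux_mat(Pb, Pb)
        else flux_mat(band_block(sp_prev$P, cfg), Pb)
  out <- cbind(mean_intensity = mean_intensity(raw),
               band_power = bp$band_power,
               band_mean_power = bp$band_mean_power,
               band_max_over_band_power = bp$band_max_over_band_power,
               spectral_centroid = mo$centroid,
               spectral_spread = mo$spread,
               spectral_skewness = mo$skewness,
               spectral_kurtosis = mo$kurtosis,
               spectral_crest = sh$crest,
               spectral_flatness = sh$flatness,
               spectral_entropy = sh$entropy,
               spectral_slope = sh$slope,
               max_frequency = pk$max_frequency,
               phasor_phase = pk$phasor_phase,
               phasor_amp = pk$phasor_amp,
               temporal_var = temporal_variance(filt),
               spectral_flux_pos = fl$flux_pos,
               spectral_flux_neg = fl$flux_neg,
               ratio_flux_pos = fl$ratio_flux_pos,
               ratio_flux_neg = fl$ratio_flux_neg)
  out[, feature_ids(), drop = FALSE]
}

#' Construct a feature map
#'
#' A 2-D grid of one feature over the ROI lattice with its identity and
#' scale metadata.
#'
#' @param values numeric matrix on the ROI lattice.
#' @param feature_id one of [feature_ids()] (or a derived id such as
#'   `"similarity"`).
#' @param t0 segment start time in seconds.
#' @param db_scaled has the decibel conversion been applied?
#' @return an object of class `feature_map`.
#' @export
feature_map <- function(values, feature_id, t0 = 0, db_scaled = FALSE) {
  stopifnot(is.matrix(values))
  structure(list(values = values, feature_id = feature_id, t0 = t0,
                 db_scaled = isTRUE(db_scaled)),
            class = "feature_map")
}

#' @export
print.feature_map <- function(x, ...) {
  cat(sprintf("<feature_map> %s, %d x %d, t0 = %g s%s\n", x$feature_id,
              nrow(x$values), ncol(x$values), x$t0,
              if (x$db_scaled) " [dB]" else ""))
  invisible(x)
}

#' Assemble the 20 feature maps of one segment
#'
#' Reshapes the per-pixel feature matrix onto the ROI lattice, one
#' [feature_map()] per feature in bank order.
#'
#' @param features matrix from [compute_feature_matrix()] (`n_pix x 20`,
#'   pixels in column-major lattice order).
#' @param lattice integer vector `c(rows, cols)` of the ROI lattice.
#' @param t0 segment start time in seconds.
#' @return named list of 20 [feature_map()] objects.
#' @export
build_maps <- function(features, lattice, t0 = 0) {
  if (anyNA(features)) stop("missing pixel values in feature matrix", call. = FALSE)
  if (nrow(features) != prod(lattice))
    stop("feature matrix does not cover the lattice", call. = FALSE)
  ids <- colnames(features)
  stopifnot(identical(sort(ids), sort(feature_ids())))
  maps <- lapply(ids, function(id)
    feature_map(matrix(features[, id], lattice[1L], lattice[2L]), id, t0))
  names(maps) <- ids
  maps[feature_ids()]
}
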