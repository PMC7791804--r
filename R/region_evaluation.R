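#' Labeled pixel region
#'
#' A labeled region on the ROI lattice used for contrast and similarity
#' evaluation: a large background region (`"BG"`) or a region expected to
#' carry pulsatility (`"PULSE"`).
#'
#' @param mask logical matrix on the lattice, or an integer rectangle
#'   `c(row1, row2, col1, col2)` interpreted within `dim` (then required).
#' @param label region tag, `"BG"` or `"PULSE"`.
#' @param dim lattice dimensions `c(rows, cols)`, required for rectangle
#'   input.
#' @return an object of class `region_spec` with the mask, label and pixel
#'   count `n_pix`.
#' @export
region_spec <- function(mask, label = c("BG", "PULSE"), dim = NULL) {
  label <- match.arg(label)
  if (!is.matrix(mask)) {
    stopifnot(length(mask) == 4L, !is.null(dim))
    m <- matrix(FALSE, dim[1L], dim[2L])
    stopifnot(mask[1L] >= 1, mask[2L] <= dim[1L], mask[3L] >= 1,
              mask[4L] <= dim[2L])
    m[mask[1L]:mask[2L], mask[3L]:mask[4L]] <- TRUE
    mask <- m
  }
  stopifnot(is.logical(mask))
  structure(list(mask = mask, label = label, n_pix = sum(mask)),
            class = "region_spec")
}

#' Read a region mask from a binary TIFF
#'
#' Nonzero pixels mark the region.
#'
#' @param path path to a single-page TIFF.
#' @inheritParams region_spec
#' @return a [region_spec()].
#' @export
read_region_mask <- function(path, label = c("BG", "PULSE")) {
  img <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  region_spec(img != 0, label = match.arg(label))
}

#' RMS contrast of a region
#'
#' The sample standard deviation (divisor `n_pix - 1`) of the map values
#' inside the region -- the RMS contrast. Computed on maps normalized to
#' `[0, 1]` so that maps with different value ranges are comparable.
#'
#' @param map a normalized [feature_map()] or bare matrix.
#' @param region a [region_spec()] with at least 2 pixels.
#' @return nonnegative contrast (dimensionless).
#' @export
rms_contrast <- function(map, region) {
  v <- if (is.matrix(map)) map else map$values
  if (!all(dim(region$mask) == dim(v)))
    stop("region mask does not match map dimensions", call. = FALSE)
  if (region$n_pix < 2L)
    stop("contrast needs at least 2 region pixels", call. = FALSE)
  stats::sd(v[region$mask])
}

#' RMS-contrast comparison report for the full bank
#'
#' One row per feature map, in bank order, with the RMS contrast of the
#' pulsatile and background regions and a flag where the pulsatile region
#' has the smaller contrast (the inverted cases -- typically the
#' max-frequency map).
#'
#' @param maps named list of normalized [feature_map()] objects (the full
#'   bank).
#' @param bg,pulse [region_spec()] objects for the background and pulsatile
#'   regions.
#' @return data frame with columns `feature_id`, `pulse`, `bg`,
#'   `pulse_lt_bg`.
#' @export
contrast_report <- function(maps, bg, pulse) {
  ids <- names(maps)
  p <- vapply(maps, rms_contrast, numeric(1L), region = pulse)
  b <- vapply(maps, rms_contrast, numeric(1L), region = bg)
  data.frame(feature_id = ids, pulse = unname(p), bg = unname(b),
             pulse_lt_bg = unname(p < b), row.names = NULL,
             stringsAsFactors = FALSE)
}
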