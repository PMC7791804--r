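#' Synthetic scene configuration
#'
#' Parameters of the deterministic synthetic video generator that stands in
#' for camera recordings: a static noisy background, a pulsatile foreground
#' (filled silhouette for PPGI-like scenes, a thin contour ring for
#' IRT-like scenes), and optional distinct-frequency sub-regions ("eyes"),
#' specular reflections carrying the pulse, global illumination flicker and
#' cast shadows.
#'
#' The pulsatile amplitude varies smoothly across the foreground (radially
#' and angularly, spanning `1 +- amp_heterogeneity` times `pulse_amp`) and
#' the pulse phase carries a lateral gradient, emulating the spatially
#' heterogeneous pulsatility and phase of real skin.
#'
#' @param rows,cols frame dimensions in pixels.
#' @param fs frame rate in Hz.
#' @param duration clip length in seconds.
#' @param pulse_freq pulse frequency in Hz, inside `(0, fs/2)`.
#' @param pulse_amp pulse amplitude in intensity units.
#' @param modulation_mode `"silhouette"` (filled ellipse, PPGI-like) or
#'   `"contour"` (ring of `contour_width` pixels, IRT-like).
#' @param noise_sd per-pixel Gaussian noise standard deviation.
#' @param noise_ar optional AR(1) coefficient in `[0, 1)` for temporally
#'   correlated sensor noise (0 = white).
#' @param baseline background intensity level.
#' @param center,semi_axes ellipse center and semi-axes `c(row, col)` in
#'   pixels; defaults place an ellipse covering ~20% of the frame.
#' @param amp_heterogeneity relative amplitude variation across the
#'   foreground, in `[0, 1)`.
#' @param phase_span lateral pulse-phase gradient across the foreground in
#'   radians.
#' @param contour_width ring width in pixels for contour mode.
#' @param secondary optional list `(center, radius, freq, amp)`: circular
#'   sub-regions (mirrored about the vertical axis, like eyes) oscillating
#'   at their own frequency instead of the pulse.
#' @param reflection optional list `(rect, gain)`: rectangle
#'   `c(row1, row2, col1, col2)` carrying `gain` times the pulse signal.
#' @param flicker optional list `(freq, amp)`: global multiplicative
#'   illumination flicker `1 + amp sin(2 pi freq t)`.
#' @param shadow optional list `(rect, amp)`: region darkening linearly by
#'   `amp` over the clip (a slowly cast shadow).
#' @param seed integer; generation is bit-reproducible given the seed.
#' @return an object of class `scene_config`.
#' @export
scene_config <- function(rows = 120L, cols = 160L, fs = 25, duration = 10,
                         pulse_freq = 1.2, pulse_amp = 1,
                         modulation_mode = c("silhouette", "contour"),
                         noise_sd = 0.3, noise_ar = 0, baseline = 100,
                         center = c(rows / 2, cols / 2),
                         semi_axes = c(0.30 * rows, 0.21 * cols),
                         amp_heterogeneity = 0.5, phase_span = 0.2 * pi,
                         contour_width = 2, secondary = NULL,
                         reflection = NULL, flicker = NULL, shadow = NULL,
                         seed = 1L) {
  modulation_mode <- match.arg(modulation_mode)
  stopifnot(rows >= 8, cols >= 8, fs > 0, duration > 0)
  if (!(pulse_freq > 0 && pulse_freq < fs / 2))
    stop("pulse_freq must lie in (0, fs/2)", call. = FALSE)
  stopifnot(pulse_amp >= 0, noise_sd >= 0, noise_ar >= 0, noise_ar < 1,
            amp_heterogeneity >= 0, amp_heterogeneity < 1)
  structure(list(rows = as.integer(rows), cols = as.integer(cols), fs = fs,
                 duration = duration, pulse_freq = pulse_freq,
                 pulse_amp = pulse_amp, modulation_mode = modulation_mode,
                 noise_sd = noise_sd, noise_ar = noise_ar,
                 baseline = baseline, center = center, semi_axes = semi_axes,
                 amp_heterogeneity = amp_heterogeneity,
                 phase_span = phase_span, contour_width = contour_width,
                 secondary = secondary, reflection = reflection,
                 flicker = flicker, shadow = shadow, seed = as.integer(seed)),
            class = "scene_config")
}

# elliptical radius field and angle field of the scene foreground
scene_fields <- function(cfg) {
  r <- matrix(seq_len(cfg$rows), cfg$rows, cfg$cols)
  c_ <- matrix(seq_len(cfg$cols), cfg$rows, cfg$cols, byrow = TRUE)
  dr <- (r - cfg$center[1L]) / cfg$semi_axes[1L]
  dc <- (c_ - cfg$center[2L]) / cfg$semi_axes[2L]
  list(rho = sqrt(dr^2 + dc^2), theta = atan2(dr, dc), dc = dc)
}

# full-resolution region masks of the scene
scene_masks <- function(cfg) {
  fl <- scene_fields(cfg)
  sil <- fl$rho <= 1
  fg <- if (cfg$modulation_mode == "silhouette") sil
        else sil & fl$rho >= 1 - cfg$contour_width / min(cfg$semi_axes)
  sec <- matrix(FALSE, cfg$rows, cfg$cols)
  if (!is.null(cfg$secondary)) {
    s <- cfg$secondary
    r <- matrix(seq_len(cfg$rows), cfg$rows, cfg$cols)
    c_ <- matrix(seq_len(cfg$cols), cfg$rows, cfg$cols, byrow = TRUE)
    for (sgn in c(-1, 1)) {
      cc <- cfg$center[2L] + sgn * abs(s$center[2L] - cfg$center[2L])
      sec <- sec | ((r - s$center[1L])^2 + (c_ - cc)^2 <= s$radius^2)
    }
  }
  refl <- matrix(FALSE, cfg$rows, cfg$cols)
  if (!is.null(cfg$reflection)) {
    rc <- cfg$reflection$rect
    refl[rc[1L]:rc[2L], rc[3L]:rc[4L]] <- TRUE
  }
  shad <- matrix(FALSE, cfg$rows, cfg$cols)
  if (!is.null(cfg$shadow)) {
    rc <- cfg$shadow$rect
    shad[rc[1L]:rc[2L], rc[3L]:rc[4L]] <- TRUE
  }
  list(silhouette = sil, foreground = fg & !sec, secondary = sec,
       reflection = refl, shadow = shad)
}

# run code under a temporary RNG seed, restoring the caller's RNG state
with_local_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Generate a synthetic scene
#'
#' Renders the clip described by a [scene_config()]:
#' `frame(t) = flicker(t) * (baseline + pulsatile and secondary terms) +
#' shadow(t) + noise`. The pulsatile term is
#' `A(x) sin(2 pi f_pulse t + phi(x))` on the foreground (filled silhouette
#' or contour ring), with the amplitude field `A` and phase field `phi`
#' described in [scene_config()]; secondary regions oscillate at their own
#' frequency; a reflection region carries a scaled copy of the pulse.
#' Gaussian noise (optionally AR(1) in time) is added everywhere.
#' Bit-reproducible for a fixed seed; the caller's RNG state is left
#' untouched.
#'
#' @param cfg a [scene_config()].
#' @return a [frame_sequence()] with modality `"synthetic"`.
#' @export
generate_scene <- function(cfg) {
  n <- as.integer(round(cfg$duration * cfg$fs))
  msk <- scene_masks(cfg)
  fl <- scene_fields(cfg)
  het <- cfg$amp_heterogeneity *
    (0.7 * cos(pi * pmin(fl$rho, 1)) + 0.3 * sin(fl$theta))
  A <- cfg$pulse_amp * (1 + het) * msk$foreground
  phi <- cfg$phase_span * fl$dc
  Ac <- A * cos(phi); As <- A * sin(phi)
  if (!is.null(cfg$reflection)) {
    g <- cfg$reflection$gain
    Ac <- Ac + g * cfg$pulse_amp * msk$reflection
  }
  S2c <- if (!is.null(cfg$secondary))
    cfg$secondary$amp * msk$secondary else NULL
  t <- (seq_len(n) - 1L) / cfg$fs
  w <- 2 * pi * cfg$pulse_freq
  out <- array(0, dim = c(cfg$rows, cfg$cols, n))
  for (k in seq_len(n)) {
    fr <- cfg$baseline + Ac * sin(w * t[k]) + As * cos(w * t[k])
    if (!is.null(S2c))
      fr <- fr + S2c * sin(2 * pi * cfg$secondary$freq * t[k])
    if (!is.null(cfg$flicker))
      fr <- fr * (1 + cfg$flicker$amp * sin(2 * pi * cfg$flicker$freq * t[k]))
    if (!is.null(cfg$shadow))
      fr <- fr - cfg$shadow$amp * (t[k] / cfg$duration) * msk$shadow
    out[, , k] <- fr
  }
  if (cfg$noise_sd > 0) {
    noise <- with_local_seed(cfg$seed,
      array(stats::rnorm(cfg$rows * cfg$cols * n), dim = dim(out)))
    if (cfg$noise_ar > 0) {
      s <- sqrt(1 - cfg$noise_ar^2)
      for (k in 2L:n)
        noise[, , k] <- cfg$noise_ar * noise[, , k - 1L] + s * noise[, , k]
    }
    out <- out + cfg$noise_sd * noise
  }
  frame_sequence(out, fs = cfg$fs, bit_depth = 16L, modality = "synthetic")
}

# lattice pixels whose full pooling support satisfies a predicate:
# "all" (support entirely inside mask) or "none" (support disjoint from it)
lattice_mask <- function(mask, pool_cfg, mode = c("all", "none")) {
  mode <- match.arg(mode)
  n <- pool_cfg$n_kernel
  cs <- t(apply(apply(mask + 0, 2L, cumsum), 1L, cumsum))
  I <- rbind(0, cbind(0, cs))  # integral image with zero border
  nr <- nrow(mask) - n + 1L; nc <- ncol(mask) - n + 1L
  ri <- seq_len(nr); ci <- seq_len(nc)
  cnt <- I[ri + n, ci + n, drop = FALSE] - I[ri, ci + n, drop = FALSE] -
    I[ri + n, ci, drop = FALSE] + I[ri, ci, drop = FALSE]
  full <- if (mode == "all") cnt == n * n else cnt == 0
  full[decimation_index(nr, pool_cfg$d_y, pool_cfg$b_center),
       decimation_index(nc, pool_cfg$d_x, pool_cfg$b_center), drop = FALSE]
}

#' Ground-truth region masks on the ROI lattice
#'
#' Maps the scene's regions onto the ROI lattice produced by a given
#' pooling configuration. Foreground lattice pixels are those whose entire
#' pooling support lies inside the pulsatile foreground (erosion by the
#' pooling footprint, so "foreground" is purely foreground); background
#' pixels are those whose support touches none of the dynamic regions
#' (foreground, secondary, reflection, shadow).
#'
#' The list also carries the evaluation regions used for the RMS-contrast
#' report, mirroring how evaluation regions are drawn by hand on real
#' recordings: `roi_pulse` is the lattice bounding box of the subject
#' silhouette (a region *expected* to show pulsatility, containing a mix of
#' strongly and weakly pulsatile pixels) and `roi_bg` is the pure
#' background mask.
#'
#' @param cfg a [scene_config()].
#' @param pool_cfg the [pooling_config()] that will be applied to the clip.
#' @return list with logical lattice masks `foreground`, `background`,
#'   `secondary`, `reflection`, `roi_pulse`, `roi_bg`, the full-resolution
#'   `masks`, and `frequencies` (`foreground`, `secondary`).
#' @export
scene_ground_truth <- function(cfg, pool_cfg) {
  msk <- scene_masks(cfg)
  active <- msk$foreground | msk$secondary | msk$reflection | msk$shadow
  bg <- lattice_mask(active, pool_cfg, "none")
  bbox <- lattice_bbox(msk$silhouette, pool_cfg)
  list(foreground = lattice_mask(msk$foreground, pool_cfg, "all"),
       background = bg,
       secondary = lattice_mask(msk$secondary, pool_cfg, "all"),
       reflection = lattice_mask(msk$reflection, pool_cfg, "all"),
       roi_pulse = bbox,
       roi_bg = bg & !bbox,
       masks = msk,
       frequencies = list(foreground = cfg$pulse_freq,
                          secondary = if (!is.null(cfg$secondary))
                            cfg$secondary$freq else NULL))
}

# lattice pixels whose pooling-support center falls inside the bounding box
# of a full-resolution mask
lattice_bbox <- function(mask, pool_cfg) {
  rr <- range(which(rowSums(mask) > 0))
  cc <- range(which(colSums(mask) > 0))
  n <- pool_cfg$n_kernel
  half <- (n - 1L) / 2
  centers <- function(nfull, d) {
    m <- (nfull - n + 1L) %/% d
    off <- if (pool_cfg$b_center) (d - 1L) %/% 2L else 0L
    off + 1L + (seq_len(m) - 1L) * d + half
  }
  ri <- centers(nrow(mask), pool_cfg$d_y)
  ci <- centers(ncol(mask), pool_cfg$d_x)
  outer(ri >= rr[1L] & ri <= rr[2L], ci >= cc[1L] & ci <= cc[2L], "&")
}
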