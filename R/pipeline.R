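#' Named processing-chain presets
#'
#' Bundled parametrizations of the full chain. The three reference presets
#' reproduce the published parametrization exactly:
#' `"paper-adult-ppgi"` (Gaussian sigma 10, kernel 41, decimation 5, filter
#' band 0.80--5 Hz, analysis band 0.85--3.98 Hz, 129 bins),
#' `"paper-baby-ppgi"` (same spatial stage, filter band 1.30--5 Hz,
#' analysis band 1.51--3.66 Hz, 89 bins) and `"paper-irt"` (sigma 5,
#' kernel 33, decimation 1, adult bands). All use 10-s segments at 25 Hz,
#' order-6 zero-phase Butterworth, Hann window, overlap 249, FFT length
#' 1024, 256 quantization levels / histogram bins and 31x31 similarity
#' patches. `"desk"` is a reduced spatial stage (sigma 2, kernel 9,
#' decimation 2, adult bands) for small synthetic scenes.
#'
#' @param name preset name.
#' @param fs sampling rate in Hz.
#' @return list with components `pooling`, `filter`, `spectral`,
#'   `similarity` and `n_scale`.
#' @export
chain_preset <- function(name = c("desk", "paper-adult-ppgi",
                                  "paper-baby-ppgi", "paper-irt"),
                         fs = 25) {
  name <- match.arg(name)
  pool <- switch(name,
    "paper-irt" = pooling_config(5, 33L, 1L, 1L, TRUE),
    "desk" = pooling_config(2, 9L, 2L, 2L, TRUE),
    pooling_config(10, 41L, 5L, 5L, TRUE))
  baby <- name == "paper-baby-ppgi"
  filt <- filter_config(t_seg = 10, fs = fs, order = 6L,
                        f_low = if (baby) 1.30 else 0.80, f_high = 5,
                        zero_phase = TRUE)
  spec <- spectral_config(n_fft = 1024L,
                          f_band_low = if (baby) 1.51 else 0.85,
                          f_band_high = if (baby) 3.66 else 3.98,
                          fs = fs, zero_pad = TRUE)
  list(name = name, pooling = pool, filter = filt, spectral = spec,
       similarity = similarity_config(256L, 31L, "symmetric"),
       n_scale = 256L)
}

# frames-x-pixels series matrix of a pooled sequence (column-major lattice)
series_matrix <- function(pooled) {
  d <- dim(pooled$frames)
  t(matrix(pooled$frames, d[1L] * d[2L], d[3L]))
}

#' Run the full processing chain
#'
#' Executes preprocessing (dropped-frame repair when timestamps are
#' present), ROI generation (Gaussian pooling and decimation), the sliding
#' temporal stage (per-segment mean removal, zero-phase bandpass, Hann
#' window), spectral transformation, the 20-feature bank, postprocessing
#' (per-feature decibel conversion, normalization to `[0, 1]`,
#' quantization), histogram-intersection similarity maps against a
#' background model, and the RMS-contrast report.
#'
#' @param input a [frame_sequence()], a [scene_config()] (the scene is
#'   generated first) or a file path for [read_frames()].
#' @param preset preset name for [chain_preset()], or a preset list.
#' @param hop segment hop in samples; default `n_seg` (non-overlapping
#'   segments -- the reference overlap of 249, i.e. hop 1, is available but
#'   expensive).
#' @param regions optional list with [region_spec()] entries `bg` and
#'   `pulse` on the ROI lattice. When `input` is a scene configuration they
#'   default to the scene's ground-truth background/foreground masks.
#' @param similarity_features feature ids for which similarity maps are
#'   computed (patch histograms are costly; the default covers the maps the
#'   reference analysis displays). `character(0)` disables.
#' @param eval_segment index of the segment used for the contrast report
#'   and similarity maps.
#' @param out_dir optional output directory; when given, maps (multi-page
#'   float TIFF plus plain-text page manifest), the contrast report (TSV)
#'   and the run manifest (YAML) are written there.
#' @return an object of class `map_run`: per-segment raw, normalized and
#'   quantized map banks, similarity maps, the contrast report, and a
#'   manifest echoing every chain parameter.
#' @export
run_pipeline <- function(input, preset = "desk", hop = NULL, regions = NULL,
                         similarity_features = c("mean_intensity",
                                                 "band_mean_power",
                                                 "temporal_var",
                                                 "spectral_flatness"),
                         eval_segment = 1L, out_dir = NULL) {
  scene_cfg <- NULL
  if (inherits(input, "scene_config")) {
    scene_cfg <- input
    input <- generate_scene(input)
  } else if (is.character(input)) {
    input <- read_frames(input)
  }
  stopifnot(inherits(input, "frame_sequence"))
  if (is.character(preset)) preset <- chain_preset(preset, fs = input$fs)

  if (!is.null(input$timestamps))
    input <- interpolate_dropped_frames(input, input$fs)
  pooled <- pool_sequence(input, preset$pooling)
  lattice <- dim(pooled$frames)[1:2]
  S <- series_matrix(pooled)

  fcfg <- preset$filter
  scfg <- preset$spectral
  if (is.null(hop)) hop <- fcfg$n_seg
  starts <- sliding_segments(nrow(S), fcfg$n_seg, hop)
  bp <- design_bandpass(fcfg, input$fs)
  w <- hann_window(fcfg$n_seg)
  win_sum <- sum(w)

  segments <- vector("list", length(starts))
  sp_prev <- NULL
  for (si in seq_along(starts)) {
    idx <- starts[si]:(starts[si] + fcfg$n_seg - 1L)
    raw <- S[idx, , drop = FALSE]
    filt <- filter_segment(raw, bp, zero_phase = fcfg$zero_phase)
    sp <- compute_spectra(filt * w, scfg, win_sum)
    fm <- compute_feature_matrix(raw, filt, sp, scfg, sp_prev = sp_prev)
    maps <- build_maps(fm, lattice, t0 = (starts[si] - 1L) / input$fs)
    norm <- lapply(maps, function(m) {
      u <- db_factor_for(m$feature_id)
      if (!is.na(u)) m <- db_convert(m, u = u)
      normalize_map(m)
    })
    quant <- lapply(norm, quantize_map, n_scale = preset$n_scale)
    segments[[si]] <- list(t0 = (starts[si] - 1L) / input$fs, maps = maps,
                           maps_norm = norm, maps_quant = quant)
    sp_prev <- sp
  }

  if (is.null(regions) && !is.null(scene_cfg)) {
    gt <- scene_ground_truth(scene_cfg, preset$pooling)
    regions <- list(bg = region_spec(gt$roi_bg, "BG"),
                    pulse = region_spec(gt$roi_pulse, "PULSE"))
  }

  contrast <- NULL
  similarity <- NULL
  if (!is.null(regions)) {
    ev <- segments[[eval_segment]]
    contrast <- contrast_report(ev$maps_norm, regions$bg, regions$pulse)
    if (length(similarity_features)) {
      similarity <- lapply(similarity_features, function(id) {
        q <- ev$maps_quant[[id]]
        h <- model_histogram(q, regions$bg, preset$similarity$n_bins)
        sm <- similarity_map(q, h, preset$similarity)
        sm$feature_id <- paste0("similarity_", id)
        sm
      })
      names(similarity) <- similarity_features
    }
  }

  manifest <- run_manifest(preset, input, lattice, hop, scene_cfg)
  run <- structure(list(segments = segments, contrast = contrast,
                        similarity = similarity, regions = regions,
                        lattice = lattice, preset = preset,
                        manifest = manifest),
                   class = "map_run")
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

#' @export
print.map_run <- function(x, ...) {
  cat(sprintf("<map_run> %d segment(s), %d x %d lattice, preset %s\n",
              length(x$segments), x$lattice[1L], x$lattice[2L],
              x$preset$name))
  invisible(x)
}

run_manifest <- function(preset, input, lattice, hop, scene_cfg) {
  fcfg <- preset$filter; scfg <- preset$spectral
  sim <- preset$similarity; pool <- preset$pooling
  list(preset = preset$name, modality = input$modality, fs = input$fs,
       n_frames = n_frames(input),
       preprocessing = list(method = "linear_interpolation",
                            n_samples = "all"),
       roi_generation = list(filter_type = "gaussian",
                             sigma_gauss = pool$sigma_gauss,
                             n_kernel = pool$n_kernel, d_x = pool$d_x,
                             d_y = pool$d_y, b_center = pool$b_center,
                             lattice_rows = lattice[1L],
                             lattice_cols = lattice[2L]),
       temporal_filtering = list(t_seg = fcfg$t_seg, n_seg = fcfg$n_seg,
                                 filter = "iir", design = "butterworth",
                                 n_order_design = fcfg$order,
                                 b_zero_phase = fcfg$zero_phase,
                                 f_half_low = fcfg$f_low,
                                 f_half_high = fcfg$f_high),
       feature_generation = list(window = "hann", n_win = fcfg$n_seg,
                                 n_overlap = fcfg$n_seg - hop, hop = hop,
                                 n_fft = scfg$n_fft,
                                 b_zero_pad = scfg$zero_pad,
                                 f_fft_low = scfg$f_band_low,
                                 f_fft_high = scfg$f_band_high,
                                 b_low = scfg$b_low, b_high = scfg$b_high,
                                 n_band = scfg$n_band),
       postprocessing = list(n_scale = preset$n_scale, n_bins = sim$n_bins,
                             n_kernel_hist = sim$n_kernel_hist,
                             padding = sim$padding),
       scene = if (!is.null(scene_cfg))
         list(seed = scene_cfg$seed, pulse_freq = scene_cfg$pulse_freq,
              pulse_amp = scene_cfg$pulse_amp,
              noise_sd = scene_cfg$noise_sd,
              modulation_mode = scene_cfg$modulation_mode))
}

write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (si in seq_along(run$segments)) {
    seg <- run$segments[[si]]
    pages <- lapply(seg$maps, function(m) m$values)
    rng <- lapply(pages, range)
    pages <- lapply(pages, function(p) normalize_map(p))
    tiff::writeTIFF(pages, file.path(out_dir, sprintf("maps_seg%03d.tiff", si)),
                    bits.per.sample = 32L)
    meta <- data.frame(page = seq_along(pages), feature_id = names(pages),
                       t0 = seg$t0,
                       min = vapply(rng, `[`, numeric(1L), 1L),
                       max = vapply(rng, `[`, numeric(1L), 2L))
    utils::write.table(meta, file.path(out_dir,
                                       sprintf("maps_seg%03d.tsv", si)),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  if (!is.null(run$contrast))
    utils::write.table(run$contrast, file.path(out_dir, "contrast.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(run$similarity)) {
    pages <- lapply(run$similarity, function(m) m$values)
    tiff::writeTIFF(pages, file.path(out_dir, "similarity.tiff"),
                    bits.per.sample = 32L)
  }
  yaml::write_yaml(run$manifest, file.path(out_dir, "manifest.yaml"))
  invisible(out_dir)
}

#' Generate and store a synthetic clip
#'
#' Thin wrapper over [generate_scene()] and [write_frames()]: renders the
#' scene, writes it as a float TIFF stack and echoes the scene parameters
#' (including the seed) in a YAML sidecar next to the clip.
#'
#' @param cfg a [scene_config()].
#' @param out output clip path (`.tiff`).
#' @return `out`, invisibly.
#' @export
simulate_clip <- function(cfg, out) {
  seq <- generate_scene(cfg)
  write_frames(seq, out, format = "tiff")
  side <- cfg[!vapply(cfg, is.null, logical(1L))]
  class(side) <- NULL
  yaml::write_yaml(side, paste0(out, ".yaml"))
  invisible(out)
}
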