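#' Construct a frame sequence
#'
#' A frame sequence is the in-memory representation of a monochrome video:
#' an ordered stack of 2-D intensity grids together with its sampling rate,
#' optional per-frame acquisition timestamps, the native bit depth and a
#' modality tag.
#'
#' @param frames numeric 3-D array (rows x cols x n_frames) or a list of
#'   equally sized matrices. Intensities are kept as real values; no
#'   rescaling is applied anywhere in the chain.
#' @param fs sampling rate in Hz (nominal frame rate).
#' @param timestamps optional numeric vector of acquisition times in seconds,
#'   one per frame, strictly increasing.
#' @param bit_depth integer, native ADC bit depth (7--16 for the supported
#'   cameras; any positive integer accepted).
#' @param modality one of `"PPGI-VIS"`, `"PPGI-NIR"`, `"IRT-LWIR"`,
#'   `"synthetic"`.
#' @return an object of class `frame_sequence`.
#' @export
frame_sequence <- function(frames, fs, timestamps = NULL, bit_depth = 16L,
                           modality = "synthetic") {
  if (is.list(frames)) {
    dims <- lapply(frames, dim)
    if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1L)
      stop("all frames must share identical dimensions", call. = FALSE)
    frames <- array(unlist(frames, use.names = FALSE),
                    dim = c(dims[[1L]], length(dims)))
  }
  if (length(dim(frames)) == 2L) frames <- array(frames, dim = c(dim(frames), 1L))
  stopifnot(length(dim(frames)) == 3L, dim(frames)[3L] >= 1L)
  storage.mode(frames) <- "double"
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("fs must be a positive scalar [Hz]", call. = FALSE)
  if (!is.null(timestamps)) {
    if (length(timestamps) != dim(frames)[3L])
      stop("one timestamp per frame required", call. = FALSE)
    if (any(diff(timestamps) <= 0))
      stop("timestamps must be strictly increasing", call. = FALSE)
  }
  modality <- match.arg(modality, c("PPGI-VIS", "PPGI-NIR", "IRT-LWIR", "synthetic"))
  structure(list(frames = frames, fs = fs, timestamps = timestamps,
                 bit_depth = as.integer(bit_depth), modality = modality),
            class = "frame_sequence")
}

#' @export
print.frame_sequence <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<frame_sequence> %d x %d pix, %d frames @ %g Hz (%.2f s), %d bit, %s\n",
              d[1L], d[2L], d[3L], x$fs, d[3L] / x$fs, x$bit_depth, x$modality))
  invisible(x)
}

#' @rdname frame_sequence
#' @param seq a `frame_sequence`.
#' @export
n_frames <- function(seq) dim(seq$frames)[3L]

#' @rdname frame_sequence
#' @export
clip_duration <- function(seq) n_frames(seq) / seq$fs

# ---- file formats ----------------------------------------------------------

#' Read a frame stack from disk
#'
#' Supported containers: multi-page TIFF (the primary exchange format) and a
#' raw little-endian unsigned-integer frame file accompanied by a plain-text
#' sidecar header (`<path>.hdr`) declaring `rows`, `cols`, `frames`,
#' `bit_depth`, `fs` and optionally `modality` and comma-separated
#' `timestamps`. Native bit depth is preserved as real values; nothing is
#' rescaled.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"tiff"` or `"raw"`.
#' @param fs sampling rate in Hz used when the container carries none
#'   (TIFF); ignored for raw files whose header declares `fs`.
#' @param modality modality tag used when the container carries none.
#' @return a [frame_sequence()].
#' @export
read_frames <- function(path, format = c("auto", "tiff", "raw"),
                        fs = 25, modality = "synthetic") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto")
    format <- if (grepl("\\.tiff?$", path, ignore.case = TRUE)) "tiff" else "raw"
  if (format == "tiff") {
    pages <- tiff::readTIFF(path, all = TRUE, info = TRUE, as.is = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    if (identical(attr(pages[[1L]], "bits.per.sample"), 32L))
      pages <- tiff::readTIFF(path, all = TRUE)  # float pages: keep as reals
    if (!is.list(pages)) pages <- list(pages)
    pages <- lapply(pages, function(p) {
      if (length(dim(p)) == 3L) p <- p[, , 1L]  # monochrome: first channel
      p
    })
    dims <- vapply(pages, function(p) paste(dim(p), collapse = "x"), "")
    if (length(unique(dims)) != 1L)
      stop("inconsistent frame dimensions in TIFF stack", call. = FALSE)
    bit_depth <- 16L
    ts <- NULL
    hdr_path <- paste0(path, ".hdr")
    if (file.exists(hdr_path)) {  # sidecar of a real-valued float stack
      hdr <- read_sidecar(hdr_path)
      if (!is.null(hdr$min)) {
        lo <- as.numeric(hdr$min); hi <- as.numeric(hdr$max)
        pages <- lapply(pages, function(p) lo + p * (hi - lo))
      }
      if (!is.null(hdr$fs)) fs <- as.numeric(hdr$fs)
      if (!is.null(hdr$modality)) modality <- hdr$modality
      if (!is.null(hdr$bit_depth)) bit_depth <- as.integer(hdr$bit_depth)
      if (!is.null(hdr$timestamps))
        ts <- as.numeric(strsplit(hdr$timestamps, ",")[[1L]])
    }
    return(frame_sequence(lapply(pages, function(p) p + 0), fs = fs,
                          timestamps = ts, bit_depth = bit_depth,
                          modality = modality))
  }
  hdr_path <- paste0(path, ".hdr")
  if (!file.exists(hdr_path)) stop("missing sidecar header: ", hdr_path, call. = FALSE)
  hdr <- read_sidecar(hdr_path)
  need <- c("rows", "cols", "frames", "bit_depth", "fs")
  if (!all(need %in% names(hdr)))
    stop("sidecar header must declare: ", paste(need, collapse = ", "), call. = FALSE)
  rows <- as.integer(hdr$rows); cols <- as.integer(hdr$cols)
  nfr <- as.integer(hdr$frames); bd <- as.integer(hdr$bit_depth)
  size <- raw_sample_size(bd)
  n <- rows * cols * nfr
  con <- file(path, "rb"); on.exit(close(con))
  v <- readBin(con, "integer", n = n, size = size, signed = size > 2L,
               endian = "little")
  if (length(v) != n) stop("raw file truncated: ", path, call. = FALSE)
  ts <- if (!is.null(hdr$timestamps))
    as.numeric(strsplit(hdr$timestamps, ",")[[1L]]) else NULL
  frame_sequence(array(as.numeric(v), dim = c(rows, cols, nfr)),
                 fs = as.numeric(hdr$fs), timestamps = ts, bit_depth = bd,
                 modality = if (!is.null(hdr$modality)) hdr$modality else modality)
}

#' Write a frame stack to disk
#'
#' For TIFF, integer-valued stacks are stored at the sequence's declared bit
#' depth (8 or 16 bits per sample) and round-trip bit-identically through
#' [read_frames()]; real-valued stacks are stored as unit-range 32-bit float
#' pages with the intensity scale, sampling rate and modality declared in a
#' plain-text sidecar header (`<path>.hdr`) so they round-trip to within
#' float precision. For raw output, frames are written as little-endian
#' unsigned integers with a sidecar header.
#'
#' @param seq a [frame_sequence()].
#' @param path output file path.
#' @param format `"auto"`, `"tiff"` or `"raw"`.
#' @return `path`, invisibly.
#' @export
write_frames <- function(seq, path, format = c("auto", "tiff", "raw")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.tiff?$", path, ignore.case = TRUE)) "tiff" else "raw"
  fr <- seq$frames
  if (format == "tiff") {
    integral <- all(fr == round(fr)) && all(fr >= 0)
    if (integral) {
      bits <- if (seq$bit_depth <= 8L) 8L else 16L
      full <- 2^bits - 1
      if (max(fr) > full) stop("intensities exceed declared bit depth", call. = FALSE)
      pages <- lapply(seq_len(dim(fr)[3L]), function(k) fr[, , k] / full)
      tiff::writeTIFF(pages, path, bits.per.sample = bits)
    } else {
      # float pages are stored unit-range; the sidecar carries the scale
      rng <- range(fr)
      span <- if (rng[2L] > rng[1L]) rng[2L] - rng[1L] else 1
      pages <- lapply(seq_len(dim(fr)[3L]),
                      function(k) (fr[, , k] - rng[1L]) / span)
      tiff::writeTIFF(pages, path, bits.per.sample = 32L)
      hdr <- c(sprintf("min: %s", format(rng[1L], digits = 17)),
               sprintf("max: %s", format(rng[1L] + span, digits = 17)),
               sprintf("fs: %g", seq$fs),
               sprintf("bit_depth: %d", seq$bit_depth),
               sprintf("modality: %s", seq$modality))
      if (!is.null(seq$timestamps))
        hdr <- c(hdr, sprintf("timestamps: %s",
                              paste(format(seq$timestamps, digits = 15),
                                    collapse = ",")))
      writeLines(hdr, paste0(path, ".hdr"))
    }
    return(invisible(path))
  }
  if (any(fr != round(fr)) || any(fr < 0))
    stop("raw format stores unsigned integers; quantize the stack first",
         call. = FALSE)
  size <- raw_sample_size(seq$bit_depth)
  con <- file(path, "wb")
  writeBin(as.integer(fr), con, size = size, endian = "little")
  close(con)
  hdr <- c(sprintf("rows: %d", dim(fr)[1L]), sprintf("cols: %d", dim(fr)[2L]),
           sprintf("frames: %d", dim(fr)[3L]),
           sprintf("bit_depth: %d", seq$bit_depth), sprintf("fs: %g", seq$fs),
           sprintf("endian: little"), sprintf("modality: %s", seq$modality))
  if (!is.null(seq$timestamps))
    hdr <- c(hdr, sprintf("timestamps: %s",
                          paste(format(seq$timestamps, digits = 15), collapse = ",")))
  writeLines(hdr, paste0(path, ".hdr"))
  invisible(path)
}

read_sidecar <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  kv <- regmatches(lines, regexec("^\\s*([^:]+?)\\s*:\\s*(.*)$", lines))
  out <- lapply(kv, function(m) m[3L])
  names(out) <- vapply(kv, function(m) m[2L], "")
  out
}

raw_sample_size <- function(bit_depth) {
  if (bit_depth <= 8L) 1L else if (bit_depth <= 16L) 2L else 4L
}

# ---- dropped-frame repair --------------------------------------------------

#' Repair dropped frames by linear interpolation
#'
#' Detects gaps in the acquisition grid -- either from timestamps (an
#' inter-frame interval exceeding 1.5x the nominal period) or from an
#' explicit list of missing grid indices -- and fills every detected gap
#' with frames linearly interpolated from the two neighboring acquired
#' frames, so the output is uniformly sampled at `nominal_fs`. Originally
#' acquired frames are never altered.
#'
#' @param seq a [frame_sequence()]; must carry timestamps unless
#'   `drop_index` is given.
#' @param nominal_fs nominal frame rate in Hz.
#' @param drop_index optional integer vector of missing positions on the
#'   uniform output grid (1-based, relative to the first acquired frame).
#' @return a uniformly sampled [frame_sequence()] without timestamps.
#' @export
interpolate_dropped_frames <- function(seq, nominal_fs, drop_index = NULL) {
  fr <- seq$frames
  n <- dim(fr)[3L]
  if (is.null(seq$timestamps) && is.null(drop_index))
    stop("need timestamps or an explicit drop index list", call. = FALSE)
  if (!is.null(seq$timestamps)) {
    ts <- seq$timestamps - seq$timestamps[1L]
    slots <- round(ts * nominal_fs) + 1L
    if (anyDuplicated(slots))
      stop("timestamps map two frames onto one grid slot", call. = FALSE)
    out_n <- slots[n]
  } else {
    drop_index <- sort(unique(as.integer(drop_index)))
    out_n <- n + length(drop_index)
    if (any(drop_index < 1L) || any(drop_index > out_n) ||
        1L %in% drop_index || out_n %in% drop_index)
      stop("gap at sequence boundary cannot be interpolated one-sided",
           call. = FALSE)
    slots <- setdiff(seq_len(out_n), drop_index)
  }
  if (out_n == n && all(slots == seq_len(n))) return(seq)
  d <- dim(fr)
  out <- array(NA_real_, dim = c(d[1L], d[2L], out_n))
  out[, , slots] <- fr
  missing <- setdiff(seq_len(out_n), slots)
  for (m in missing) {
    lo <- max(slots[slots < m]); hi <- min(slots[slots > m])
    a <- (m - lo) / (hi - lo)
    out[, , m] <- (1 - a) * out[, , lo] + a * out[, , hi]
  }
  frame_sequence(out, fs = nominal_fs, bit_depth = seq$bit_depth,
                 modality = seq$modality)
}
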