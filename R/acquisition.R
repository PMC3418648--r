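#' Ultrasound acquisition configuration
#'
#' Describes the probe and digitisation settings of an RF or B-mode
#' recording.  Defaults reproduce a high-frequency biomicroscope setup for
#' small-animal carotid imaging: 40 MHz centre frequency (110% fractional
#' bandwidth at -6 dB), 500 MHz / 8-bit sampling and 60 frames/s.
#'
#' @param center_frequency probe centre frequency, Hz.
#' @param sampling_frequency axial (RF) sampling frequency, Hz.
#' @param frame_rate frames per second.
#' @param speed_of_sound assumed tissue sound speed, m/s.
#' @param lateral_pitch_um distance between adjacent scan lines, micrometres.
#'   Not reported by typical scanners' spec sheets at this level; 30 um is a
#'   plausible value for a 40 MHz biomicroscope (use ~300 um for a cardiac
#'   probe).
#' @param bit_depth sample bit depth used when exporting integer data.
#' @param fractional_bandwidth pulse fractional bandwidth at -6 dB
#'   (dimensionless; 1.1 = 110%).
#' @param lateral_beamwidth_um -6 dB two-way lateral beam width, micrometres.
#'
#' @return An object of class `acq_config`.
#' @export
acquisition_config <- function(center_frequency = 40e6,
                               sampling_frequency = 500e6,
                               frame_rate = 60,
                               speed_of_sound = 1540,
                               lateral_pitch_um = 30,
                               bit_depth = 8L,
                               fractional_bandwidth = 1.1,
                               lateral_beamwidth_um = 80) {
  x <- list(center_frequency = center_frequency,
            sampling_frequency = sampling_frequency,
            frame_rate = frame_rate,
            speed_of_sound = speed_of_sound,
            lateral_pitch_um = lateral_pitch_um,
            bit_depth = as.integer(bit_depth),
            fractional_bandwidth = fractional_bandwidth,
            lateral_beamwidth_um = lateral_beamwidth_um)
  for (nm in names(x))
    if (!is.numeric(x[[nm]]) || length(x[[nm]]) != 1L || !is.finite(x[[nm]]) ||
        x[[nm]] <= 0)
      stop_fmt("acquisition_config: '%s' must be a positive scalar", nm)
  structure(x, class = "acq_config")
}

#' Axial sample spacing
#'
#' Distance between consecutive RF samples along the beam,
#' `speed_of_sound / (2 * sampling_frequency)`.
#'
#' @param acq an [acquisition_config()].
#' @return Spacing in micrometres.
#' @export
axial_spacing_um <- function(acq) {
  stopifnot(inherits(acq, "acq_config"))
  acq$speed_of_sound / (2 * acq$sampling_frequency) * 1e6
}

#' Convert a physical window size to samples
#'
#' Window extents quoted in micrometres (axial x lateral) are converted to
#' (samples, lines) using the axial sample spacing and the lateral line
#' pitch, rounding to the nearest integer and clamping at 1.
#'
#' @param size_um numeric length-2, c(axial_um, lateral_um).
#' @param acq an [acquisition_config()].
#' @return Integer length-2 c(axial_samples, lateral_lines).
#' @export
um_to_samples <- function(size_um, acq) {
  stopifnot(length(size_um) == 2L, all(size_um > 0))
  c(max(1L, as.integer(round(size_um[1] / axial_spacing_um(acq)))),
    max(1L, as.integer(round(size_um[2] / acq$lateral_pitch_um))))
}

#' RF / B-mode sequence container
#'
#' A stack of co-registered 2D frames (axis 1 = axial/depth, axis 2 =
#' lateral/scan line) with its acquisition metadata.
#'
#' @param frames numeric 3D array `[axial, lateral, frame]`, at least 2
#'   frames.
#' @param acq an [acquisition_config()].
#' @param modality `"RF"` (raw echo samples) or `"BMODE"` (envelope image).
#' @return Object of class `rf_sequence`.
#' @export
rf_sequence <- function(frames, acq, modality = c("RF", "BMODE")) {
  modality <- match.arg(modality)
  if (!is.array(frames) || length(dim(frames)) != 3L)
    stop_fmt("rf_sequence: 'frames' must be a 3D array [axial, lateral, frame]")
  if (dim(frames)[3] < 2L)
    stop_fmt("rf_sequence: need at least 2 frames, got %d", dim(frames)[3])
  stopifnot(inherits(acq, "acq_config"))
  structure(list(frames = frames, acq = acq, modality = modality),
            class = "rf_sequence")
}

#' @export
print.rf_sequence <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<rf_sequence> %s, %d frames of %d x %d (axial x lateral)\n",
              x$modality, d[3], d[1], d[2]))
  cat(sprintf("  f0 = %.1f MHz, fs = %.1f MHz, %g fps, axial spacing %.3f um\n",
              x$acq$center_frequency / 1e6, x$acq$sampling_frequency / 1e6,
              x$acq$frame_rate, axial_spacing_um(x$acq)))
  invisible(x)
}

n_frames <- function(seq) dim(seq$frames)[3]

#' Quantize a sequence to its configured bit depth
#'
#' Internal pipeline values are real-valued; quantization happens only on
#' export.  The symmetric amplitude range is mapped linearly to
#' `[0, 2^bit_depth - 1]` with the zero level at mid-scale.
#'
#' @param seq an [rf_sequence()].
#' @return An `rf_sequence` of integers in `[0, 2^bit_depth - 1]`, with
#'   attributes `scale` and `offset` to invert the mapping.
#' @export
quantize_sequence <- function(seq) {
  stopifnot(inherits(seq, "rf_sequence"))
  b <- seq$acq$bit_depth
  top <- 2^b - 1
  amax <- max(abs(seq$frames))
  if (amax == 0) amax <- 1
  q <- round((seq$frames / amax + 1) / 2 * top)
  q <- array(pmin(pmax(q, 0), top), dim = dim(seq$frames))
  out <- rf_sequence(q, seq$acq, seq$modality)
  attr(out, "scale") <- 2 * amax / top
  attr(out, "offset") <- -amax
  out
}

fields_acq <- c("center_frequency", "sampling_frequency", "frame_rate",
                "speed_of_sound", "lateral_pitch_um", "bit_depth",
                "fractional_bandwidth", "lateral_beamwidth_um")

#' Write / read an RF or B-mode sequence
#'
#' The container is a raw little-endian binary payload (`<path>`) plus a
#' plain-text JSON sidecar (`<path>.json`) holding the full acquisition
#' header, modality, array dimensions and payload dtype.  Integer data
#' (`dtype = "uint8"`) round-trips bit-exactly; `"float64"` stores doubles
#' exactly.
#'
#' @param seq an [rf_sequence()].
#' @param path payload file path (the sidecar gets a `.json` suffix).
#' @param dtype `"float64"` or `"uint8"`.  `"uint8"` requires integer values
#'   in `[0, 255]` (see [quantize_sequence()]).
#' @return `write_sequence`: the path, invisibly.  `read_sequence`: an
#'   `rf_sequence`.
#' @export
write_sequence <- function(seq, path, dtype = c("float64", "uint8")) {
  stopifnot(inherits(seq, "rf_sequence"))
  dtype <- match.arg(dtype)
  v <- as.vector(seq$frames)
  if (dtype == "uint8") {
    if (any(v != round(v)) || any(v < 0) || any(v > 255))
      stop_fmt("write_sequence: uint8 requires integer samples in [0, 255]")
  }
  hdr <- list(format = "imbiomark-sequence", version = 1L,
              modality = seq$modality, dim = dim(seq$frames), dtype = dtype,
              acq = seq$acq[fields_acq])
  jsonlite::write_json(hdr, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  con <- file(path, "wb")
  on.exit(close(con))
  if (dtype == "uint8") writeBin(as.raw(v), con)
  else writeBin(as.double(v), con, size = 8, endian = "little")
  invisible(path)
}

#' @rdname write_sequence
#' @export
read_sequence <- function(path) {
  side <- paste0(path, ".json")
  if (!file.exists(path)) stop_fmt("read_sequence: no payload file '%s'", path)
  if (!file.exists(side)) stop_fmt("read_sequence: no sidecar '%s'", side)
  hdr <- jsonlite::read_json(side, simplifyVector = TRUE)
  for (f in c("format", "modality", "dim", "dtype", "acq"))
    if (is.null(hdr[[f]]))
      stop_fmt("read_sequence: header field '%s' missing", f)
  if (!identical(hdr$format, "imbiomark-sequence"))
    stop_fmt("read_sequence: header field 'format' is '%s', not an imbiomark sequence",
             hdr$format)
  dm <- as.integer(hdr$dim)
  if (length(dm) != 3L)
    stop_fmt("read_sequence: header field 'dim' must have 3 entries")
  n <- prod(dm)
  bytes <- if (hdr$dtype == "uint8") 1 else 8
  if (file.info(path)$size != n * bytes)
    stop_fmt(paste0("read_sequence: header field 'dim' promises %d samples ",
                    "(%d bytes) but payload has %d bytes"),
             n, n * bytes, file.info(path)$size)
  con <- file(path, "rb")
  on.exit(close(con))
  v <- if (hdr$dtype == "uint8") as.double(readBin(con, "raw", n))
       else readBin(con, "double", n, size = 8, endian = "little")
  acq <- do.call(acquisition_config, lapply(hdr$acq[fields_acq], as.double))
  rf_sequence(array(v, dim = dm), acq, hdr$modality)
}

#' Wall segmentation masks
#'
#' Per-frame label grids marking the vessel anatomy.  Labels:
#' 0 = background, 1 = near wall, 2 = far wall, 3 = lumen.
#'
#' @param labels integer 3D array `[axial, lateral, frame]` of labels 0-3.
#' @return Object of class `wall_mask`.
#' @export
wall_mask <- function(labels) {
  if (!is.array(labels) || length(dim(labels)) != 3L)
    stop_fmt("wall_mask: 'labels' must be a 3D array [axial, lateral, frame]")
  u <- unique(as.vector(labels))
  if (!all(u %in% 0:3))
    stop_fmt("wall_mask: labels must be in {0 background, 1 near, 2 far, 3 lumen}")
  structure(list(labels = array(as.integer(labels), dim(labels))),
            class = "wall_mask")
}

#' @rdname wall_mask
#' @export
mask_labels <- c(background = 0L, near_wall = 1L, far_wall = 2L, lumen = 3L)

#' Write / read a wall mask as run-length text
#'
#' Line 1 is a JSON header with the array dimensions; the remainder is a CSV
#' of `frame,value,length` runs in column-major order within each frame.
#'
#' @param mask a [wall_mask()].
#' @param path file path.
#' @param seq optional [rf_sequence()] to validate the mask shape against.
#' @return `read_mask`: a `wall_mask`.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "wall_mask"))
  dm <- dim(mask$labels)
  runs <- lapply(seq_len(dm[3]), function(f) {
    r <- rle(as.integer(mask$labels[, , f]))
    data.frame(frame = f, value = r$values, length = r$lengths)
  })
  runs <- do.call(rbind, runs)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(as.character(jsonlite::toJSON(
    list(format = "imbiomark-mask", dim = dm), auto_unbox = TRUE)), con)
  writeLines("frame,value,length", con)
  writeLines(sprintf("%d,%d,%d", runs$frame, runs$value, runs$length), con)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path, seq = NULL) {
  lines <- readLines(path)
  hdr <- jsonlite::fromJSON(lines[1])
  if (!identical(hdr$format, "imbiomark-mask"))
    stop_fmt("read_mask: '%s' is not an imbiomark mask file", path)
  dm <- as.integer(hdr$dim)
  tab <- read.csv(text = lines[-1])
  lab <- array(NA_integer_, dm)
  for (f in seq_len(dm[3])) {
    r <- tab[tab$frame == f, ]
    lab[, , f] <- inverse.rle(list(values = r$value, lengths = r$length))
  }
  m <- wall_mask(lab)
  if (!is.null(seq)) {
    ds <- dim(seq$frames)
    if (!identical(dim(m$labels), ds))
      stop_fmt("read_mask: mask shape %s does not match sequence shape %s",
               paste(dim(m$labels), collapse = "x"),
               paste(ds, collapse = "x"))
  }
  m
}

#' Write / read tidy result tables
#'
#' Plain CSV with a stable column order (the order of the data frame given).
#'
#' @param table a data.frame.
#' @param path file path.
#' @return `read_results`: a data.frame.
#' @export
write_results <- function(table, path) {
  stopifnot(is.data.frame(table))
  write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) read.csv(path, stringsAsFactors = FALSE)

#' Export a B-mode sequence as a multi-page TIFF
#'
#' @param seq an [rf_sequence()] with values in `[0, 1]` (see
#'   [render_bmode()]).
#' @param path output TIFF path.
#' @export
write_bmode_tiff <- function(seq, path) {
  stopifnot(inherits(seq, "rf_sequence"))
  pages <- lapply(seq_len(n_frames(seq)), function(k) {
    m <- seq$frames[, , k]
    pmin(pmax(m, 0), 1)
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  invisible(path)
}
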