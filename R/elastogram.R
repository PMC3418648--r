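#' Measurement-window grid
#'
#' Lays half-open measurement windows over a frame with the given overlap.
#' The step per axis is `max(1, round((1 - overlap) * extent))`; the count
#' is `floor((frame_extent - window_extent) / step) + 1`.
#'
#' @param frame_dim integer c(axial, lateral) frame shape.
#' @param window integer c(axial, lateral) window extents, samples.
#' @param overlap fractional overlap in both axes (scalar or length-2),
#'   e.g. 0.9.
#' @return A list: `window`, `step`, `n` (grid counts), `starts_ax`,
#'   `starts_lat` (1-based window start indices), `frame_dim`.
#' @export
build_grid <- function(frame_dim, window, overlap = 0.9) {
  frame_dim <- as.integer(frame_dim); window <- as.integer(window)
  overlap <- rep(overlap, length.out = 2L)
  stopifnot(length(frame_dim) == 2L, length(window) == 2L,
            all(overlap >= 0), all(overlap < 1))
  if (any(window > frame_dim))
    stop_fmt("build_grid: window %s does not fit in frame %s",
             paste(window, collapse = "x"), paste(frame_dim, collapse = "x"))
  if (any(window < 1L)) stop_fmt("build_grid: window extents must be >= 1")
  step <- pmax(1L, as.integer(round((1 - overlap) * window)))
  n <- (frame_dim - window) %/% step + 1L
  list(window = window, step = step, n = n,
       starts_ax = 1L + step[1] * (seq_len(n[1]) - 1L),
       starts_lat = 1L + step[2] * (seq_len(n[2]) - 1L),
       frame_dim = frame_dim)
}

# fractional centre (axial, lateral) of grid cell (ia, il), frame coords
grid_centers <- function(grid) {
  list(ax = grid$starts_ax + (grid$window[1] - 1) / 2,
       lat = grid$starts_lat + (grid$window[2] - 1) / 2)
}

#' Axial strain elastogram of one frame pair
#'
#' Collects the axial-strain component of a [estimate_frame_pair()] motion
#' field onto the window grid.  The display/reporting convention makes
#' wall compression positive (systole) and dilation negative (diastole);
#' the raw engineering strain is the negated value and the convention is
#' recorded in the `sign` attribute.
#'
#' @param field a `motion_field`.
#' @param frame_pair index of the (t, t+dt) pair this field belongs to.
#' @param drop_nonconverged treat non-converged windows as missing.
#' @return Object of class `elastogram`: list with `values` (matrix, grid
#'   layout, `NA` = missing), `grid`, `frame_pair`.
#' @export
elastogram_from_field <- function(field, frame_pair = 1L,
                                  drop_nonconverged = TRUE) {
  stopifnot(inherits(field, "motion_field"))
  v <- -field$Dyy                       # compression positive
  v[field$missing] <- NA_real_
  if (drop_nonconverged) v[!field$converged] <- NA_real_
  structure(list(values = v, grid = field$grid,
                 frame_pair = as.integer(frame_pair)),
            class = "elastogram", sign = "compression_positive")
}

#' Track a whole sequence into an elastogram stack
#'
#' Runs the windowed affine estimator over every consecutive frame pair and
#' assembles the axial-strain elastograms.  The measurement-window size is
#' given in micrometres (converted through the acquisition geometry) with
#' 90% overlap by default.  When a wall mask is supplied only windows whose
#' centre lies in the selected wall band(s) are estimated — for attenuated
#' high-frequency RF data the near wall alone is the reliable choice.
#'
#' @param seq an [rf_sequence()].
#' @param mask optional [wall_mask()] aligned with `seq`.
#' @param wall wall band(s) to track when `mask` is given.
#' @param window_um measurement-window size, micrometres (axial, lateral).
#' @param overlap fractional window overlap.
#' @param search translation search radius c(axial, lateral), samples.
#' @param exclude optional logical matrix of samples to exclude (e.g.
#'   registration fill); `NA` samples in the frames are always excluded.
#' @param ... passed to [estimate_frame_pair()].
#' @return Object of class `elastogram_stack`: `values` array
#'   `[grid_ax, grid_lat, n_pairs]`, `grid`, `acq`, `wall`.
#' @export
track_sequence <- function(seq, mask = NULL, wall = "near",
                           window_um = c(108, 312), overlap = 0.9,
                           search = c(10L, 3L), exclude = NULL, ...) {
  stopifnot(inherits(seq, "rf_sequence"))
  win <- um_to_samples(window_um, seq$acq)
  grid <- build_grid(dim(seq$frames)[1:2], win, overlap)
  n <- n_frames(seq)
  vals <- array(NA_real_, c(grid$n[1], grid$n[2], n - 1L))
  for (k in seq_len(n - 1L)) {
    mframe <- if (!is.null(mask)) mask$labels[, , k] else NULL
    fld <- estimate_frame_pair(seq$frames[, , k], seq$frames[, , k + 1L],
                               grid, search = search, exclude = exclude,
                               mask = mframe, wall = wall, ...)
    vals[, , k] <- elastogram_from_field(fld, k)$values
  }
  structure(list(values = vals, grid = grid, acq = seq$acq, wall = wall),
            class = "elastogram_stack", sign = "compression_positive")
}

#' @export
print.elastogram_stack <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<elastogram_stack> %d frame pair(s), %d x %d window grid, %.1f%% cells present\n",
              d[3], d[1], d[2], 100 * mean(!is.na(x$values))))
  invisible(x)
}

#' Restrict an elastogram to a wall band
#'
#' Windows whose centre sample lies outside the selected wall label(s) are
#' set missing.  Works on a single `elastogram` (with the matching mask
#' frame) or on a whole `elastogram_stack`.
#'
#' @param x an `elastogram` or `elastogram_stack`.
#' @param mask a [wall_mask()]; for a single elastogram, its frame `k` is
#'   used where `k` is the elastogram's `frame_pair`.
#' @param wall `"near"`, `"far"`, or both.
#' @return Same class as `x`.
#' @export
apply_segmentation <- function(x, mask, wall = c("near", "far")) {
  wall <- match.arg(wall, several.ok = TRUE)
  keep_labels <- mask_labels[paste0(wall, "_wall")]
  seg_one <- function(values, grid, labels) {
    cen <- grid_centers(grid)
    ia <- round(cen$ax); il <- round(cen$lat)
    keep <- matrix(labels[cbind(rep(ia, times = length(il)),
                                rep(il, each = length(ia)))] %in% keep_labels,
                   length(ia), length(il))
    values[!keep] <- NA_real_
    values
  }
  if (inherits(x, "elastogram")) {
    x$values <- seg_one(x$values, x$grid, mask$labels[, , x$frame_pair])
    return(x)
  }
  stopifnot(inherits(x, "elastogram_stack"))
  for (k in seq_len(dim(x$values)[3]))
    x$values[, , k] <- seg_one(x$values[, , k], x$grid, mask$labels[, , k])
  x$wall <- wall
  x
}

#' Median post-filter on the window grid
#'
#' Replaces every non-missing elastogram cell by the median of the
#' non-missing values in its `size` x `size` neighbourhood of window-grid
#' cells (5 x 5 by default).  Missing cells stay missing.
#'
#' @param x an `elastogram` or `elastogram_stack`.
#' @param size odd neighbourhood size in grid cells.
#' @return Same class as `x`.
#' @export
median_filter <- function(x, size = 5L) {
  stopifnot(size %% 2 == 1, size >= 1)
  h <- (size - 1L) %/% 2L
  filt <- function(v) {
    n1 <- nrow(v); n2 <- ncol(v)
    out <- v
    for (i in seq_len(n1)) {
      ri <- max(1L, i - h):min(n1, i + h)
      for (j in seq_len(n2)) {
        if (is.na(v[i, j])) next
        nb <- v[ri, max(1L, j - h):min(n2, j + h)]
        out[i, j] <- median(nb, na.rm = TRUE)
      }
    }
    out
  }
  if (inherits(x, "elastogram")) { x$values <- filt(x$values); return(x) }
  stopifnot(inherits(x, "elastogram_stack"))
  for (k in seq_len(dim(x$values)[3])) x$values[, , k] <- filt(x$values[, , k])
  x
}

#' Render an elastogram over a B-mode background
#'
#' Produces an RGB raster: grey B-mode background with the strain overlay
#' in a diverging palette — blue for positive (compression/systole), yellow
#' for negative (dilation/diastole) — and missing cells transparent
#' (background visible).  The elastogram grid is mapped back to image
#' coordinates by nearest-window assignment.
#'
#' @param el an `elastogram`.
#' @param bmode optional background matrix in `[0, 1]` with the original
#'   frame shape.
#' @param limits symmetric colour limits, fraction strain (default: max
#'   absolute value present).
#' @return An `[ny, nx, 3]` RGB array in `[0, 1]` with attribute
#'   `limits_pct` (colour-bar range in percent strain).
#' @export
render_elastogram <- function(el, bmode = NULL, limits = NULL) {
  stopifnot(inherits(el, "elastogram"))
  nd <- el$grid$frame_dim
  if (is.null(bmode)) bmode <- matrix(0, nd[1], nd[2])
  if (is.null(limits)) {
    v <- abs(el$values[!is.na(el$values)])
    limits <- if (length(v) && max(v) > 0) max(v) else 0.01
  }
  pal <- grDevices::colorRamp(c("#ffe014", "#ffffff", "#1f3cff"))
  out <- array(rep(pmin(pmax(bmode, 0), 1), 3), c(nd[1], nd[2], 3))
  cen <- grid_centers(el$grid)
  half <- pmax(1, el$grid$step / 2)
  for (ia in seq_len(el$grid$n[1])) {
    rows <- max(1, round(cen$ax[ia] - half[1])):min(nd[1], round(cen$ax[ia] + half[1]))
    for (il in seq_len(el$grid$n[2])) {
      v <- el$values[ia, il]
      if (is.na(v)) next
      cols <- max(1, round(cen$lat[il] - half[2])):min(nd[2], round(cen$lat[il] + half[2]))
      u <- (max(min(v, limits), -limits) / limits + 1) / 2
      rgb <- pal(u)[1, ] / 255
      for (ch in 1:3) out[rows, cols, ch] <- rgb[ch]
    }
  }
  attr(out, "limits_pct") <- c(-limits, limits) * 100
  out
}
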