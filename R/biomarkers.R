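#' Mean axial strain (MAS) curve over a region of interest
#'
#' Averages the non-missing elastogram cells of a fixed ROI for every frame
#' pair, giving the MAS time series in percent strain (compression
#' positive).  Default ROI sizes follow common practice: 5 x 9 grid cells
#' (axial x lateral) for high-frequency rodent RF data, 3 x 9 for human
#' ascending-aorta B-mode data.  Without explicit placement the ROI is
#' centred on the grid cell with the largest time-averaged strain
#' magnitude (the most strongly pulsating part of the wall band).
#'
#' @param stack an `elastogram_stack` (see [track_sequence()]).
#' @param roi optional list with integer vectors `ax`, `lat` of grid-cell
#'   indices; overrides automatic placement.
#' @param roi_size integer c(axial, lateral) ROI size in grid cells.
#' @param frame_rate frames per second (default from the stack's
#'   acquisition config), stored for cycle detection.
#' @return Object of class `mas_curve`: list with `strain_pct` (length
#'   n_pairs), `roi`, `frame_rate`, `gaps` (frame pairs where the whole ROI
#'   was missing).
#' @export
mas_curve <- function(stack, roi = NULL, roi_size = c(5L, 9L),
                      frame_rate = NULL) {
  stopifnot(inherits(stack, "elastogram_stack"))
  if (is.null(frame_rate)) frame_rate <- stack$acq$frame_rate
  d <- dim(stack$values)
  if (is.null(roi)) {
    roi_size <- pmin(as.integer(roi_size), d[1:2])
    mag <- apply(abs(stack$values), c(1, 2), mean, na.rm = TRUE)
    mag[!is.finite(mag)] <- -Inf
    # centre the ROI on the strongest cell, clamped inside the grid
    k <- which(mag == max(mag), arr.ind = TRUE)[1, ]
    h <- (roi_size - 1L) %/% 2L
    a0 <- min(max(k[1] - h[1], 1L), d[1] - roi_size[1] + 1L)
    l0 <- min(max(k[2] - h[2], 1L), d[2] - roi_size[2] + 1L)
    roi <- list(ax = a0:(a0 + roi_size[1] - 1L),
                lat = l0:(l0 + roi_size[2] - 1L))
  }
  stopifnot(all(roi$ax >= 1), all(roi$ax <= d[1]),
            all(roi$lat >= 1), all(roi$lat <= d[2]))
  sub <- stack$values[roi$ax, roi$lat, , drop = FALSE]
  strain <- 100 * apply(sub, 3, mean, na.rm = TRUE)
  gaps <- which(!is.finite(strain))
  strain[gaps] <- NA_real_
  structure(list(strain_pct = strain, roi = roi, frame_rate = frame_rate,
                 gaps = gaps),
            class = "mas_curve")
}

#' @export
print.mas_curve <- function(x, ...) {
  cat(sprintf("<mas_curve> %d frame pairs, range [%.2f, %.2f]%% strain%s\n",
              length(x$strain_pct), min(x$strain_pct, na.rm = TRUE),
              max(x$strain_pct, na.rm = TRUE),
              if (length(x$gaps)) sprintf(", %d gap(s)", length(x$gaps))
              else ""))
  invisible(x)
}

#' Detect cardiac cycles on a MAS curve
#'
#' Without an ECG the cycle period is estimated from the autocorrelation of
#' the strain series (parabolically refined), systolic peaks are anchored
#' at the global maximum and located per expected cycle, and diastolic
#' troughs likewise from the global minimum.  With an ECG channel, cycles
#' are gated by its R-peaks instead.  Peaks and troughs strictly
#' interleave.
#'
#' @param curve a [mas_curve()] (or plain numeric vector of % strain).
#' @param expected_rate optional known heart rate, beats/min (bypasses the
#'   autocorrelation period estimate; requires `frame_rate`).
#' @param ecg optional ECG series sampled once per frame pair.
#' @param frame_rate frames per second; taken from `curve` when available.
#' @return List of class `cycle_set`: `peaks`, `troughs` (frame-pair
#'   indices), `period` (frames).
#' @export
detect_cycles <- function(curve, expected_rate = NULL, ecg = NULL,
                          frame_rate = NULL) {
  y <- if (inherits(curve, "mas_curve")) curve$strain_pct else as.numeric(curve)
  if (inherits(curve, "mas_curve") && is.null(frame_rate))
    frame_rate <- curve$frame_rate
  n <- length(y)
  if (anyNA(y)) y <- approx_fill(y)
  if (sd(y) == 0)
    stop_fmt("detect_cycles: constant curve, no periodicity; supply the period manually")

  if (!is.null(ecg)) {
    r <- local_peaks(ecg, thresh = mean(range(ecg)))
    if (length(r) < 3)
      stop_fmt("detect_cycles: fewer than 2 complete ECG-gated cycles")
    peaks <- troughs <- integer(0)
    for (i in seq_len(length(r) - 1L)) {
      seg <- r[i]:(r[i + 1L] - 1L)
      peaks <- c(peaks, seg[which.max(y[seg])])
      troughs <- c(troughs, seg[which.min(y[seg])])
    }
    period <- mean(diff(r))
  } else {
    if (!is.null(expected_rate)) {
      if (is.null(frame_rate))
        stop_fmt("detect_cycles: expected_rate needs a frame_rate")
      period <- frame_rate * 60 / expected_rate
    } else {
      a <- acf(y, lag.max = floor(n / 2), plot = FALSE,
               demean = TRUE)$acf[-1]
      lags <- 2:length(a)
      p0 <- lags[which.max(a[lags])]
      d <- if (p0 > 2 && p0 < length(a))
        parabolic_offset(-a[p0 - 1], -a[p0], -a[p0 + 1]) else 0
      period <- p0 + d
      if (a[p0] < 0.2)
        stop_fmt("detect_cycles: no clear periodicity (autocorrelation peak %.2f); supply expected_rate", a[p0])
    }
    locate <- function(v, anchor) {
      pos <- anchor + period * ((-ceiling(n / period)):ceiling(n / period))
      pos <- pos[pos >= 1 - 0.25 * period & pos <= n + 0.25 * period]
      idx <- integer(0)
      for (p in pos) {
        w <- max(1L, ceiling(p - period / 2)):min(n, floor(p + period / 2))
        if (!length(w)) next
        idx <- c(idx, w[1] - 1L + which.max(v[w]))
      }
      idx <- unique(idx)
      # amplitude guard: an edge window over a truncated cycle picks a
      # flank sample; require a quarter of the anchor's elevation above
      # the curve median
      med <- median(v)
      idx <- idx[v[idx] >= med + 0.25 * (max(v) - med)]
      # non-maximum suppression: windows at the series edges can pick the
      # same flank twice; keep the stronger of any pair closer than half a
      # period
      idx <- idx[order(v[idx], decreasing = TRUE)]
      kept <- integer(0)
      for (i in idx)
        if (!length(kept) || min(abs(kept - i)) > period / 2)
          kept <- c(kept, i)
      sort(kept)
    }
    peaks <- locate(y, which.max(y))
    # the autocorrelation lag is integer-limited; re-estimate the period
    # from the located peak spacing and relocate once (drift over several
    # cycles otherwise admits spurious edge peaks)
    if (length(peaks) > 2) {
      period <- (max(peaks) - min(peaks)) / (length(peaks) - 1)
      peaks <- locate(y, which.max(y))
    }
    troughs <- locate(-y, which.min(y))
    if (length(peaks) < 2)
      stop_fmt("detect_cycles: fewer than 2 cycles detected")
  }
  structure(list(peaks = peaks, troughs = troughs, period = period),
            class = "cycle_set")
}

approx_fill <- function(y) {
  ok <- which(!is.na(y))
  if (length(ok) < 2) stop_fmt("curve has too few valid samples")
  stats::approx(ok, y[ok], xout = seq_along(y), rule = 2)$y
}

local_peaks <- function(x, thresh = -Inf) {
  n <- length(x)
  which(x >= thresh &
          x >= c(-Inf, x[-n]) & x > c(x[-1], -Inf))
}

# indices of the k most central elements of a sorted index vector
central_k <- function(idx, k) {
  m <- length(idx)
  if (m <= k) return(idx)
  s <- (m - k) %/% 2L
  idx[(s + 1L):(s + k)]
}

#' Cyclic stiffness summary of a MAS curve
#'
#' Two biomarker modes:
#' \describe{
#'   \item{`peak`}{PSS = mean of the systolic peak strains over
#'     `n_cycles` cycles; PDS = mean of the diastolic trough magnitudes
#'     over the same cycles.  Used for rodent carotid RF data.}
#'   \item{`mean`}{MSS / MDS = per-cycle means of the positive-strain
#'     (systolic) and negative-strain (diastolic) samples, averaged over
#'     `n_cycles` cycles, plus `mean_strain = (|MSS| + |MDS|) / 2` — robust
#'     to a systole/diastole offset.  Used for human ascending-aorta
#'     B-mode data.}
#' }
#' The `n_cycles` most central of the detected cycles are used (the first
#' and last cycles of a recording are the most often truncated).
#'
#' @param curve a [mas_curve()].
#' @param cycles a [detect_cycles()] result (computed when `NULL`).
#' @param mode `"peak"` or `"mean"`.
#' @param n_cycles number of cardiac cycles to average (default 3).
#' @param subject,group,side,wall,recording label columns carried into the
#'   summary row.
#' @return A one-row data.frame (a stiffness summary): labels plus
#'   `pss`/`pds` or `mss`/`mds`/`mean_strain` (% strain) and
#'   `n_cycles_used`.
#' @export
summarize_stiffness <- function(curve, cycles = NULL,
                                mode = c("peak", "mean"), n_cycles = 3L,
                                subject = NA_character_,
                                group = NA_character_,
                                side = NA_character_, wall = NA_character_,
                                recording = NA_integer_) {
  mode <- match.arg(mode)
  stopifnot(inherits(curve, "mas_curve"))
  if (is.null(cycles)) cycles <- detect_cycles(curve)
  y <- curve$strain_pct
  if (length(cycles$peaks) < n_cycles)
    stop_fmt("summarize_stiffness: %d cycle(s) detected but %d required",
             length(cycles$peaks), n_cycles)
  pk <- central_k(cycles$peaks, n_cycles)
  tr <- central_k(cycles$troughs, n_cycles)
  base <- data.frame(subject = subject, group = group, side = side,
                     wall = wall, recording = recording,
                     stringsAsFactors = FALSE)
  if (mode == "peak") {
    out <- cbind(base, data.frame(pss = mean(y[pk]), pds = mean(abs(y[tr])),
                                  n_cycles_used = length(pk)))
  } else {
    half <- cycles$period / 2
    cyc_stat <- function(centers, sign) {
      vapply(centers, function(p) {
        w <- max(1L, ceiling(p - half)):min(length(y), floor(p + half))
        v <- y[w][sign * y[w] > 0]
        if (!length(v)) NA_real_ else mean(v)
      }, numeric(1))
    }
    mss <- mean(cyc_stat(pk, +1), na.rm = TRUE)
    mds <- mean(cyc_stat(tr, -1), na.rm = TRUE)
    out <- cbind(base, data.frame(mss = mss, mds = mds,
                                  mean_strain = (abs(mss) + abs(mds)) / 2,
                                  n_cycles_used = length(pk)))
  }
  out
}

#' Pool stiffness summaries into virtual observations
#'
#' Standard pooling schemes used to enlarge small study populations:
#' \describe{
#'   \item{`rat_side_phase`}{One observation per animal x side (L/R) x
#'     cycle phase (systole = PSS, diastole = PDS): 4 virtual observations
#'     per animal.}
#'   \item{`human_wall_triplicate`}{One observation per subject x recording
#'     (triplicate) x wall (near/far), using the phase-averaged mean
#'     strain: 6 virtual observations per subject.}
#'   \item{`none`}{Identity: one row per summary, multiplier 1.}
#' }
#'
#' @param summaries a data.frame of [summarize_stiffness()] rows.
#' @param scheme pooling scheme.
#' @return A data.frame with one row per pooled observation (columns:
#'   labels, `strain`), with attribute `multiplier` = product of pooled
#'   factor level counts.
#' @export
pool_measurements <- function(summaries,
                              scheme = c("rat_side_phase",
                                         "human_wall_triplicate", "none")) {
  scheme <- match.arg(scheme)
  if (scheme == "rat_side_phase") {
    need <- c("subject", "side", "pss", "pds")
    if (!all(need %in% names(summaries)))
      stop_fmt("pool_measurements: rat_side_phase needs columns %s",
               paste(need, collapse = ", "))
    long <- rbind(
      data.frame(subject = summaries$subject, group = summaries$group,
                 side = summaries$side, phase = "systole",
                 strain = summaries$pss, stringsAsFactors = FALSE),
      data.frame(subject = summaries$subject, group = summaries$group,
                 side = summaries$side, phase = "diastole",
                 strain = summaries$pds, stringsAsFactors = FALSE))
    long <- long[order(long$subject, long$side, long$phase), ]
    rownames(long) <- NULL
    mult <- length(unique(long$side)) * length(unique(long$phase))
  } else if (scheme == "human_wall_triplicate") {
    need <- c("subject", "wall", "recording", "mean_strain")
    if (!all(need %in% names(summaries)))
      stop_fmt("pool_measurements: human_wall_triplicate needs columns %s",
               paste(need, collapse = ", "))
    long <- data.frame(subject = summaries$subject, group = summaries$group,
                       wall = summaries$wall,
                       recording = summaries$recording,
                       strain = summaries$mean_strain,
                       stringsAsFactors = FALSE)
    long <- long[order(long$subject, long$recording, long$wall), ]
    rownames(long) <- NULL
    mult <- length(unique(long$wall)) * length(unique(long$recording))
  } else {
    vcol <- intersect(c("pss", "mean_strain"), names(summaries))[1]
    long <- summaries
    long$strain <- summaries[[vcol]]
    mult <- 1L
  }
  attr(long, "multiplier") <- mult
  long
}
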