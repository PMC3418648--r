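#' Apply a rigid transform to a frame
#'
#' Rotates the content by `rot_deg` about the image centre and then shifts
#' it by `(dy, dx)` samples (axial, lateral), resampling bilinearly.
#' Samples mapped from outside the field of view are filled with `fill`
#' (`NA` by default) so downstream windows can exclude them.
#'
#' @param frame numeric matrix.
#' @param dy,dx axial / lateral shift, samples (may be fractional).
#' @param rot_deg rotation, degrees (counter-clockwise in (axial, lateral)
#'   coordinates).
#' @param inverse apply the inverse transform instead.
#' @param fill value for out-of-view samples.
#' @return A matrix of the same shape.
#' @export
apply_rigid <- function(frame, dy, dx, rot_deg, inverse = FALSE, fill = NA) {
  ny <- nrow(frame); nx <- ncol(frame)
  cy <- (ny + 1) / 2; cx <- (nx + 1) / 2
  th <- rot_deg * pi / 180
  co <- cos(th); si <- sin(th)
  gy <- matrix(seq_len(ny), ny, nx) - cy
  gx <- matrix(seq_len(nx), ny, nx, byrow = TRUE) - cx
  if (!inverse) {
    # content moved by (R, t): out(p) = in(R^-1 * (p - t))
    py <- gy - dy; px <- gx - dx
    sy <- co * py + si * px
    sx <- -si * py + co * px
  } else {
    sy <- co * gy - si * gx + dy
    sx <- si * gy + co * gx + dx
  }
  sy <- sy + cy; sx <- sx + cx
  i0 <- floor(sy); j0 <- floor(sx)
  # clamp the top edge so exact integer coordinates on the last row/column
  # stay in view
  i0 <- pmin(i0, ny - 1); j0 <- pmin(j0, nx - 1)
  fy <- sy - i0; fx <- sx - j0
  ok <- i0 >= 1 & sy <= ny & j0 >= 1 & sx <= nx & sy >= 1 & sx >= 1
  out <- matrix(fill, ny, nx)
  if (any(ok)) {
    i0k <- i0[ok]; j0k <- j0[ok]; fyk <- fy[ok]; fxk <- fx[ok]
    idx <- function(i, j) frame[cbind(i, j)]
    out[ok] <- (1 - fyk) * (1 - fxk) * idx(i0k, j0k) +
      fyk * (1 - fxk) * idx(i0k + 1, j0k) +
      (1 - fyk) * fxk * idx(i0k, j0k + 1) +
      fyk * fxk * idx(i0k + 1, j0k + 1)
  }
  out
}

parabolic_offset <- function(m1, m0, p1) {
  den <- m1 - 2 * m0 + p1
  if (!is.finite(den) || den >= 0) return(0)
  d <- 0.5 * (m1 - p1) / den
  max(min(d, 0.5), -0.5)
}

#' Rigid registration of one frame to a reference
#'
#' Finds the rigid transform (axial shift, lateral shift, rotation about
#' the centre) whose application to the reference best matches the moving
#' frame, by exhaustive normalized cross-correlation over a coarse grid
#' (1 sample, `rot_step` degrees) refined by local parabolic fits.
#'
#' @param moving,reference numeric matrices of equal shape.
#' @param max_shift integer search radius, samples (default: 10% of the
#'   smaller image dimension, at least 4).
#' @param max_rot rotation search radius, degrees.
#' @param rot_step coarse rotation step, degrees.
#' @return A list of class `rigid_transform`: `dy`, `dx` (samples), `rot`
#'   (degrees), `ncc` (score at the optimum).
#' @export
register_frame <- function(moving, reference, max_shift = NULL, max_rot = 5,
                           rot_step = 0.5) {
  stopifnot(identical(dim(moving), dim(reference)))
  if (sd(reference) == 0 || sd(moving, na.rm = TRUE) == 0 ||
      all(is.na(moving)))
    stop_fmt("register_frame: flat or empty frame; registration is degenerate")
  if (is.null(max_shift)) max_shift <- max(4L, round(0.1 * min(dim(moving))))
  mov <- moving
  mov[is.na(mov)] <- mean(mov, na.rm = TRUE)
  # correlate over an interior crop: border fill rotates with the candidate
  # angle and would otherwise bias the rotation peak
  marg <- min(ceiling(sin(max_rot * pi / 180) * max(dim(moving)) / 2) + 3L,
              (min(dim(moving)) - 8L) %/% 2L)
  ri <- (1 + marg):(nrow(moving) - marg)
  ci <- (1 + marg):(ncol(moving) - marg)
  sweep_rots <- function(rots) {
    scores <- numeric(length(rots))
    peaks <- vector("list", length(rots))
    for (r in seq_along(rots)) {
      un <- apply_rigid(mov, 0, 0, rots[r], inverse = TRUE,
                        fill = mean(mov))
      ncc <- ncc_lags_cpp(reference[ri, ci], un[ri, ci], max_shift, max_shift)
      ncc[is.na(ncc)] <- -Inf
      k <- which(ncc == max(ncc), arr.ind = TRUE)[1, ]
      scores[r] <- ncc[k[1], k[2]]
      peaks[[r]] <- list(ncc = ncc, k = k)
    }
    list(rots = rots, scores = scores, peaks = peaks,
         r = which.max(scores))
  }
  # coarse rotation grid, then a local fine grid around its optimum
  co <- sweep_rots(seq(-max_rot, max_rot, by = rot_step))
  fine_step <- rot_step / 5
  fi <- sweep_rots(seq(co$rots[co$r] - rot_step, co$rots[co$r] + rot_step,
                       by = fine_step))
  r <- fi$r
  rots <- fi$rots; scores <- fi$scores
  rot_step <- fine_step
  best <- list(score = scores[r], r = r)
  ncc <- fi$peaks[[r]]$ncc; k <- fi$peaks[[r]]$k
  # subsample shift by parabolic fit on the NCC surface
  dyc <- k[1] - max_shift - 1; dxc <- k[2] - max_shift - 1
  ddy <- if (k[1] > 1 && k[1] < nrow(ncc))
    parabolic_offset(ncc[k[1] - 1, k[2]], ncc[k[1], k[2]], ncc[k[1] + 1, k[2]])
  else 0
  ddx <- if (k[2] > 1 && k[2] < ncol(ncc))
    parabolic_offset(ncc[k[1], k[2] - 1], ncc[k[1], k[2]], ncc[k[1], k[2] + 1])
  else 0
  drot <- if (r > 1 && r < length(rots))
    rot_step * parabolic_offset(scores[r - 1], scores[r], scores[r + 1])
  else 0
  rot <- rots[r] + drot
  # the shift was found on the unrotated moving frame: map back through R
  th <- rot * pi / 180
  sy <- dyc + ddy; sx <- dxc + ddx
  structure(list(dy = cos(th) * sy - sin(th) * sx,
                 dx = sin(th) * sy + cos(th) * sx,
                 rot = rot, ncc = best$score),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("<rigid_transform> dy = %.3f, dx = %.3f samples, rot = %.3f deg (NCC %.4f)\n",
              x$dy, x$dx, x$rot, x$ncc))
  invisible(x)
}

#' Stabilize a sequence by rigid registration
#'
#' Registers every frame to a fixed reference frame (the first, by default)
#' and resamples it with the inverse transform, removing bulk
#' cardiac/respiratory motion prior to tissue strain tracking.  Out-of-view
#' samples become `NA` and are excluded from downstream measurement
#' windows.
#'
#' @param seq an [rf_sequence()] (typically B-mode).
#' @param reference index of the reference frame.
#' @param ... passed to [register_frame()].
#' @return A list: `seq` (stabilized sequence) and `transforms`
#'   (data.frame: frame, dy, dx, rot, ncc).
#' @export
register_sequence <- function(seq, reference = 1L, ...) {
  stopifnot(inherits(seq, "rf_sequence"))
  n <- n_frames(seq)
  ref <- seq$frames[, , reference]
  out <- seq$frames
  tr <- data.frame(frame = seq_len(n), dy = 0, dx = 0, rot = 0, ncc = 1)
  for (k in seq_len(n)) {
    if (k == reference) next
    t_k <- tryCatch(register_frame(seq$frames[, , k], ref, ...),
                    error = function(e)
                      stop_fmt("register_sequence: frame %d: %s", k,
                               conditionMessage(e)))
    out[, , k] <- apply_rigid(seq$frames[, , k], t_k$dy, t_k$dx, t_k$rot,
                              inverse = TRUE)
    tr[k, 2:5] <- c(t_k$dy, t_k$dx, t_k$rot, t_k$ncc)
  }
  list(seq = rf_sequence(out, seq$acq, seq$modality), transforms = tr)
}
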