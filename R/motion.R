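#' Translation between two speckle patches by cross-correlation
#'
#' Integer lag = argmax of normalized cross-correlation within the search
#' range, refined to subsample precision by a parabolic fit of the
#' correlation peak along each axis.
#'
#' @param win_t,win_t2 numeric matrices of equal shape (the measurement
#'   window at times t and t + dt).
#' @param max_lag integer length-2 c(axial, lateral) search radius; default
#'   half the window in each dimension.
#' @param subsample apply parabolic subsample refinement.
#' @return Named vector `c(T1, T2)` (lateral, axial displacement in
#'   samples; positive = content moved deeper / to higher line index), with
#'   attributes `lag` (integer peak lag, axial then lateral), `ncc` (peak
#'   correlation) and `converged` (`FALSE` when the peak lies on the search
#'   boundary).
#' @export
estimate_translation <- function(win_t, win_t2, max_lag = NULL,
                                 subsample = TRUE) {
  stopifnot(identical(dim(win_t), dim(win_t2)))
  if (anyNA(win_t) || anyNA(win_t2))
    stop_fmt("estimate_translation: window contains missing samples")
  if (sd(win_t) == 0 || sd(win_t2) == 0)
    stop_fmt("estimate_translation: constant patch; translation is degenerate")
  if (is.null(max_lag))
    max_lag <- pmax(1L, dim(win_t) %/% 2L)
  max_lag <- as.integer(rep(max_lag, length.out = 2L))
  ncc <- ncc_lags_cpp(win_t, win_t2, max_lag[1], max_lag[2])
  ncc[is.na(ncc)] <- -Inf
  k <- which(ncc == max(ncc), arr.ind = TRUE)[1, ]
  on_edge <- k[1] == 1L || k[1] == nrow(ncc) ||
    (ncol(ncc) > 1L && (k[2] == 1L || k[2] == ncol(ncc)))
  lag <- c(axial = k[1] - max_lag[1] - 1L, lateral = k[2] - max_lag[2] - 1L)
  t2 <- as.numeric(lag[1]); t1 <- as.numeric(lag[2])
  if (subsample && !on_edge) {
    if (k[1] > 1 && k[1] < nrow(ncc))
      t2 <- t2 + parabolic_offset(ncc[k[1] - 1, k[2]], ncc[k[1], k[2]],
                                  ncc[k[1] + 1, k[2]])
    if (k[2] > 1 && k[2] < ncol(ncc))
      t1 <- t1 + parabolic_offset(ncc[k[1], k[2] - 1], ncc[k[1], k[2]],
                                  ncc[k[1], k[2] + 1])
  }
  structure(c(T1 = t1, T2 = t2), lag = lag, ncc = max(ncc),
            converged = !on_edge)
}

#' Affine deformation of a measurement window
#'
#' Minimises the sum of squared differences between the window at time t
#' and the bicubically warped window at t + dt over the six affine
#' parameters (two translations and the 2x2 deformation matrix: lateral
#' strain, axial strain and the two shears), by damped Gauss-Newton
#' iterative least squares initialized at the cross-correlation translation
#' and a zero deformation matrix.  Deformation entries are bounded at
#' `bound` to prevent divergence on decorrelated speckle.
#'
#' @param win_t,win_t2 numeric matrices of equal shape, each dimension at
#'   least 4 samples.
#' @param init initial `c(T1, T2)`; computed by [estimate_translation()]
#'   when `NULL`.
#' @param frame_t2 optional full frame (or padded patch) containing
#'   `win_t2`, for sampling warped coordinates beyond the window edge.
#' @param offset position (axial, lateral, 0-based) of `win_t`'s origin
#'   inside `frame_t2`; required with `frame_t2`.
#' @param max_iter,tol Gauss-Newton iteration cap and parameter-update
#'   stopping tolerance.
#' @param bound bound on the deformation-matrix entries.
#' @return Object of class `affine_motion`: list with `T1`, `T2`, `Dxx`,
#'   `Dxy`, `Dyx`, `Dyy`, `residual` (final SSD normalized by the window
#'   energy), `converged`, `iters`, `n_used`.
#' @export
estimate_deformation <- function(win_t, win_t2, init = NULL,
                                 frame_t2 = NULL, offset = c(0, 0),
                                 max_iter = 50L, tol = 1e-6, bound = 0.2) {
  stopifnot(all(dim(win_t) >= 4L))
  if (is.null(frame_t2)) {
    stopifnot(identical(dim(win_t), dim(win_t2)))
    frame_t2 <- win_t2
    offset <- c(0, 0)
  }
  if (is.null(init)) {
    tr <- estimate_translation(win_t, win_t2)
    init <- as.numeric(tr)
  }
  fit <- lsme_gn_cpp(win_t, frame_t2, offset[1], offset[2],
                     c(init[1], init[2], 0, 0, 0, 0),
                     as.integer(max_iter), tol, bound)
  structure(list(T1 = fit$par[1], T2 = fit$par[2], Dxx = fit$par[3],
                 Dxy = fit$par[4], Dyx = fit$par[5], Dyy = fit$par[6],
                 residual = fit$residual, converged = fit$converged,
                 iters = fit$iters, n_used = fit$n_used),
            class = "affine_motion")
}

#' @export
print.affine_motion <- function(x, ...) {
  cat(sprintf("<affine_motion> T = (%.3f, %.3f), Dyy = %.5f, Dxx = %.5f, shear = (%.5f, %.5f)\n",
              x$T1, x$T2, x$Dyy, x$Dxx, x$Dxy, x$Dyx))
  cat(sprintf("  residual %.4g, %s in %d iteration(s), %d sample(s)\n",
              x$residual, if (isTRUE(x$converged)) "converged" else
                "NOT converged", x$iters, x$n_used))
  invisible(x)
}

# does window [s, s+ext) overlap any TRUE in `excl`?
window_overlaps <- function(excl, s_ax, s_lat, ext) {
  any(excl[s_ax:(s_ax + ext[1] - 1L), s_lat:(s_lat + ext[2] - 1L)])
}

#' Affine motion field over a window grid
#'
#' Runs [estimate_translation()] + [estimate_deformation()] for every
#' measurement window of `grid` between two consecutive frames.  Windows
#' overlapping an excluded region, containing missing (`NA`) samples, or
#' whose centre falls outside the selected wall labels are marked missing.
#'
#' @param frame_t,frame_t2 numeric matrices of equal shape.
#' @param grid a window layout from [build_grid()].
#' @param search integer c(axial, lateral) translation search radius,
#'   samples.  Inter-frame tissue motion is small, so this is much tighter
#'   than the single-window default.
#' @param exclude optional logical matrix; windows overlapping `TRUE` are
#'   skipped.
#' @param mask optional [wall_mask()] frame (integer label matrix); with
#'   `wall`, windows whose centre label is not among the requested labels
#'   are skipped.
#' @param wall `"near"`, `"far"`, or both.
#' @param ... passed to [estimate_deformation()].
#' @return Object of class `motion_field`: list of matrices (grid layout)
#'   `T1`, `T2`, `Dxx`, `Dxy`, `Dyx`, `Dyy`, `residual`, logical
#'   `converged` and `missing`, plus the `grid`.
#' @export
estimate_frame_pair <- function(frame_t, frame_t2, grid, search = c(10L, 3L),
                                exclude = NULL, mask = NULL,
                                wall = c("near", "far"), ...) {
  stopifnot(identical(dim(frame_t), dim(frame_t2)))
  if (!length(grid$n) || any(grid$n < 1L))
    stop_fmt("estimate_frame_pair: empty window grid")
  wall <- match.arg(wall, several.ok = TRUE)
  keep_labels <- mask_labels[paste0(wall, "_wall")]
  ext <- grid$window
  search <- as.integer(rep(search, length.out = 2L))
  pad <- search + pmax(2L, ceiling(0.2 * ext / 2)) + 3L
  dims <- dim(frame_t)
  mk <- function() matrix(NA_real_, grid$n[1], grid$n[2])
  out <- list(T1 = mk(), T2 = mk(), Dxx = mk(), Dxy = mk(), Dyx = mk(),
              Dyy = mk(), residual = mk(),
              converged = matrix(FALSE, grid$n[1], grid$n[2]),
              missing = matrix(TRUE, grid$n[1], grid$n[2]),
              grid = grid)
  if (!is.null(mask) && inherits(mask, "wall_mask"))
    stop_fmt("estimate_frame_pair: pass a single mask frame (labels[, , k]), not the whole wall_mask")
  for (ia in seq_len(grid$n[1])) {
    s_ax <- grid$starts_ax[ia]
    for (il in seq_len(grid$n[2])) {
      s_lat <- grid$starts_lat[il]
      if (!is.null(exclude) && window_overlaps(exclude, s_ax, s_lat, ext))
        next
      if (!is.null(mask)) {
        cen <- c(s_ax + (ext[1] - 1L) %/% 2L, s_lat + (ext[2] - 1L) %/% 2L)
        if (!(mask[cen[1], cen[2]] %in% keep_labels)) next
      }
      rows <- s_ax:(s_ax + ext[1] - 1L)
      cols <- s_lat:(s_lat + ext[2] - 1L)
      p1 <- frame_t[rows, cols, drop = FALSE]
      p2 <- frame_t2[rows, cols, drop = FALSE]
      if (anyNA(p1) || anyNA(p2)) next
      tr <- tryCatch(estimate_translation(p1, p2, max_lag = search),
                     error = function(e) NULL)
      if (is.null(tr)) next
      r0 <- max(1L, s_ax - pad[1]); r1 <- min(dims[1], s_ax + ext[1] - 1L + pad[1])
      c0 <- max(1L, s_lat - pad[2]); c1 <- min(dims[2], s_lat + ext[2] - 1L + pad[2])
      p2big <- frame_t2[r0:r1, c0:c1, drop = FALSE]
      if (anyNA(p2big)) p2big[is.na(p2big)] <- 0
      est <- estimate_deformation(p1, p2, init = as.numeric(tr),
                                  frame_t2 = p2big,
                                  offset = c(s_ax - r0, s_lat - c0), ...)
      out$T1[ia, il] <- est$T1; out$T2[ia, il] <- est$T2
      out$Dxx[ia, il] <- est$Dxx; out$Dxy[ia, il] <- est$Dxy
      out$Dyx[ia, il] <- est$Dyx; out$Dyy[ia, il] <- est$Dyy
      out$residual[ia, il] <- est$residual
      out$converged[ia, il] <- isTRUE(est$converged)
      out$missing[ia, il] <- FALSE
    }
  }
  structure(out, class = "motion_field")
}
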