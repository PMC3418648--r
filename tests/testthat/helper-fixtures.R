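# Shared fixtures: small speckle frames built through the phantom renderer,
# plus independent (pure-R) oracles for bicubic warping and SSD search.

fast_acq <- function(...) acquisition_config(...)

# fully developed speckle over the whole (nz x nx) frame
speckle_frame <- function(seed, nz = 200, nx = 24, acq = fast_acq(),
                          density_mm2 = 5000) {
  dz <- axial_spacing_um(acq)
  area_mm2 <- (nz * dz) * (nx * acq$lateral_pitch_um) / 1e6
  sc <- imbiomark:::with_seed(seed, {
    n <- max(50L, stats::rpois(1, density_mm2 * area_mm2))
    data.frame(z_um = stats::runif(n, 0, nz * dz),
               x_um = stats::runif(n, 0, nx * acq$lateral_pitch_um),
               amp = stats::rnorm(n), region = "wall")
  })
  list(frame = render_rf_frame(sc, acq, c(nz, nx)), scatterers = sc,
       acq = acq)
}

# --- independent bicubic oracle (cubic convolution form, a = -0.5) --------
cubic_kernel <- function(t, a = -0.5) {
  at <- abs(t)
  ifelse(at <= 1, (a + 2) * at^3 - (a + 3) * at^2 + 1,
         ifelse(at < 2, a * at^3 - 5 * a * at^2 + 8 * a * at - 4 * a, 0))
}

# sample img (matrix) at fractional 0-based coords; NA outside the stencil
oracle_bicubic <- function(img, y, x) {
  ny <- nrow(img); nx <- ncol(img)
  ok <- y >= 1 & y < ny - 2 & x >= 1 & x < nx - 2
  out <- rep(NA_real_, length(y))
  if (!any(ok)) return(out)
  yy <- y[ok]; xx <- x[ok]
  iy <- floor(yy); ix <- floor(xx)
  acc <- 0
  for (a in -1:2) for (b in -1:2) {
    w <- cubic_kernel(yy - (iy + a)) * cubic_kernel(xx - (ix + b))
    acc <- acc + w * img[cbind(iy + a + 1, ix + b + 1)]
  }
  out[ok] <- acc
  out
}

# Build a measurement-window pair with known affine truth: p1 is a window of
# `frame`; p2 is frame resampled through the inverse affine map, so the
# estimator model p1(i,j) = p2(warp(i,j; theta)) holds at theta = truth.
# theta = c(T1, T2, Dxx, Dxy, Dyx, Dyy), 0-based window coords.
warped_pair <- function(frame, rows, cols, theta) {
  p1 <- frame[rows, cols]
  n <- length(rows); m <- length(cols)
  cy <- (n - 1) / 2; cx <- (m - 1) / 2
  # (dy2, dx2) = A (dy, dx) + (T2, T1),  A = [[1+Dyy, Dyx], [Dxy, 1+Dxx]]
  A <- matrix(c(1 + theta[6], theta[4], theta[5], 1 + theta[3]), 2, 2)
  Ainv <- solve(A)
  g <- expand.grid(i = 0:(n - 1), j = 0:(m - 1))
  # forward warp of p2 grid coords back into p1/frame coords
  dy <- g$i - cy; dx <- g$j - cx
  src <- cbind(dy - theta[2], dx - theta[1]) %*% t(Ainv)
  ys <- src[, 1] + cy + (rows[1] - 1)
  xs <- src[, 2] + cx + (cols[1] - 1)
  p2 <- matrix(oracle_bicubic(frame, ys, xs), n, m)
  stopifnot(!anyNA(p2))
  list(p1 = p1, p2 = p2)
}

# brute-force SSD grid search over the axial strain alone (T and other
# parameters held at their true values, default 0)
ssd_grid_search <- function(p1, p2, dyy_grid, t2 = 0) {
  n <- nrow(p1); m <- ncol(p1)
  cy <- (n - 1) / 2; cx <- (m - 1) / 2
  g <- expand.grid(i = 0:(n - 1), j = 0:(m - 1))
  best <- c(NA_real_, Inf)
  for (e in dyy_grid) {
    ys <- g$i + t2 + e * (g$i - cy)
    v <- oracle_bicubic(p2, ys, g$j)
    ok <- !is.na(v)
    ssd <- sum((p1[cbind(g$i + 1, g$j + 1)][ok] - v[ok])^2) / sum(ok)
    if (ssd < best[2]) best <- c(e, ssd)
  }
  best[1]
}

# elastogram_stack built directly from a value array (grid bookkeeping only)
stack_from_values <- function(vals, acq = fast_acq()) {
  grid <- build_grid(c(dim(vals)[1] * 4 + 16, dim(vals)[2] + 8), c(17, 9),
                     overlap = c(1 - 4 / 17, 1 - 1 / 9))
  grid$n <- dim(vals)[1:2]
  structure(list(values = vals, grid = grid, acq = acq, wall = "near"),
            class = "elastogram_stack", sign = "compression_positive")
}

# mas_curve object from a raw % strain series
curve_from_series <- function(y, frame_rate = 60) {
  structure(list(strain_pct = y, roi = NULL, frame_rate = frame_rate,
                 gaps = integer(0)),
            class = "mas_curve")
}
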