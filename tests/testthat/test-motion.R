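acq <- acquisition_config()

test_that("translation: identity, exact integer lag, subsample shifts, degenerate input", {
  sp <- speckle_frame(21, nz = 220, nx = 16)
  w <- sp$frame[61:130, 4:13]
  t0 <- estimate_translation(w, w)
  expect_equal(as.numeric(t0), c(0, 0))
  expect_true(attr(t0, "converged"))

  # content 3 samples deeper in the second window: integer lag exact
  w2 <- sp$frame[58:127, 4:13]
  tr <- estimate_translation(w, w2, max_lag = c(10, 3))
  expect_identical(unname(attr(tr, "lag")), c(3L, 0L))
  expect_lt(abs(tr[["T2"]] - 3), 0.05)
  expect_lt(abs(tr[["T1"]]), 0.05)

  # 0.4-sample axial shift rendered from displaced scatterers
  dz <- axial_spacing_um(acq)
  sc <- sp$scatterers
  sc$z_um <- sc$z_um + 0.4 * dz
  f2 <- render_rf_frame(sc, acq, c(220, 16))
  ts <- estimate_translation(w, f2[61:130, 4:13], max_lag = c(10, 3))
  expect_lt(abs(ts[["T2"]] - 0.4), 0.1)

  expect_error(estimate_translation(matrix(2, 16, 8), w[1:16, 1:8]),
               "degenerate")

  # peak on the search boundary is flagged
  w3 <- sp$frame[55:124, 4:13]
  tb <- estimate_translation(w, w3, max_lag = c(5, 2))
  expect_false(attr(tb, "converged"))
})

test_that("affine deformation recovers warped strain and joint translation-strain", {
  sp <- speckle_frame(33, nz = 260, nx = 24)
  rows <- 101:164; cols <- 7:18

  w <- sp$frame[rows, cols]
  ident <- estimate_deformation(w, w, init = c(0, 0))
  expect_lt(abs(ident$Dyy), 1e-6)
  expect_lt(abs(ident$Dxx), 1e-6)
  expect_lt(ident$residual, 1e-10)
  expect_true(ident$converged)

  pair <- warped_pair(sp$frame, rows, cols, c(0, 0, 0, 0, 0, 0.01))
  est <- estimate_deformation(pair$p1, pair$p2)
  expect_lt(abs(est$Dyy - 0.01), 5e-4)

  pair2 <- warped_pair(sp$frame, rows, cols, c(0, 1.5, 0, 0, 0, -0.02))
  est2 <- estimate_deformation(pair2$p1, pair2$p2)
  expect_lt(abs(est2$T2 - 1.5), 0.1)
  expect_lt(abs(est2$Dyy + 0.02), 1e-3)
})

test_that("estimates are invariant to where the window sits in the padded frame", {
  sp <- speckle_frame(17, nz = 260, nx = 24)
  theta <- c(0.3, 0.7, 0, 0, 0, 0.008)
  rows <- 101:164; cols <- 7:18
  p1 <- sp$frame[rows, cols]
  # one large warped patch, two different crops both holding real content
  big <- warped_pair(sp$frame, 93:172, 3:22, theta)$p2
  crop <- big[3:78, 2:19]
  b <- estimate_deformation(p1, NULL, init = theta[1:2], frame_t2 = big,
                            offset = c(8, 4))
  d <- estimate_deformation(p1, NULL, init = theta[1:2], frame_t2 = crop,
                            offset = c(6, 3))
  expect_lt(abs(b$Dyy - d$Dyy), 1e-6)
  expect_lt(abs(b$T2 - d$T2), 1e-6)
  expect_lt(abs(b$Dyy - theta[6]), 5e-4)
})

test_that("frame-pair fields: zero field on identical frames, median accuracy on uniform strain, masking rules", {
  sp <- speckle_frame(29, nz = 300, nx = 24)
  grid <- build_grid(c(300, 24), c(48, 10), overlap = c(0.75, 0.5))

  fld0 <- estimate_frame_pair(sp$frame, sp$frame, grid, search = c(4, 2))
  expect_true(all(abs(fld0$Dyy[!fld0$missing]) < 1e-6))

  # uniform 2% axial compression of all scatterers about the frame top
  sc <- sp$scatterers
  sc$z_um <- sc$z_um * (1 - 0.02)
  f2 <- render_rf_frame(sc, acq, c(300, 24))
  fld <- estimate_frame_pair(sp$frame, f2, grid, search = c(8, 2))
  est <- stats::median(fld$Dyy[!fld$missing & fld$converged], na.rm = TRUE)
  expect_lt(abs(-est - 0.02), 0.002)   # raw Dyy is negative under compression

  # a window overlapping an excluded region is missing
  excl <- matrix(FALSE, 300, 24)
  excl[1:60, ] <- TRUE
  flde <- estimate_frame_pair(sp$frame, f2, grid, search = c(8, 2),
                              exclude = excl)
  expect_true(all(flde$missing[1:2, ]))
  expect_false(all(flde$missing))

  # center-outside-label windows are skipped
  mask <- matrix(mask_labels[["background"]], 300, 24)
  mask[101:200, ] <- mask_labels[["near_wall"]]
  fldm <- estimate_frame_pair(sp$frame, f2, grid, search = c(8, 2),
                              mask = mask, wall = "near")
  cen <- grid$starts_ax + (grid$window[1] - 1L) %/% 2L
  expect_true(all(fldm$missing[cen < 101 | cen > 200, ]))
  expect_true(all(!fldm$missing[cen >= 101 & cen <= 200, ]))

  expect_error(estimate_frame_pair(sp$frame, f2,
                                   list(n = c(0L, 0L), window = c(4L, 4L))),
               "empty")
})

test_that("optimizer matches a brute-force SSD grid search within one grid step", {
  devs <- vapply(1:6, function(s) {
    sp <- speckle_frame(100 + s, nz = 140, nx = 22)
    rows <- 61:92; cols <- 4:19          # 32 x 16 window
    e <- c(-0.015, -0.006, 0.004, 0.009, 0.013, 0.018)[s]
    pair <- warped_pair(sp$frame, rows, cols, c(0, 0, 0, 0, 0, e))
    opt <- estimate_deformation(pair$p1, pair$p2)$Dyy
    grid <- ssd_grid_search(pair$p1, pair$p2,
                            seq(e - 0.004, e + 0.004, by = 1e-4))
    abs(opt - grid)
  }, numeric(1))
  expect_lt(max(devs), 1e-4 + 1e-9)
})
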