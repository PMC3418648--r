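acq <- acquisition_config()

test_that("window grid counts match the closed form and brute-force enumeration", {
  g <- build_grid(c(256, 64), c(70, 9), overlap = 0.9)
  expect_identical(g$step, c(7L, 1L))
  expect_identical(g$n, c(27L, 56L))

  expect_identical(build_grid(c(50, 20), c(50, 20), 0.9)$n, c(1L, 1L))

  g0 <- build_grid(c(100, 30), c(20, 10), overlap = 0)
  expect_identical(g0$n, c(100L %/% 20L, 30L %/% 10L))

  expect_error(build_grid(c(40, 10), c(50, 5)), "does not fit")

  # enumeration oracle over randomized cases
  imbiomark:::with_seed(42, {
    for (i in 1:100) {
      fd <- c(sample(30:300, 1), sample(8:80, 1))
      w <- c(sample(4:min(60, fd[1]), 1), sample(2:min(16, fd[2]), 1))
      ov <- runif(1, 0, 0.95)
      g <- build_grid(fd, w, ov)
      for (ax in 1:2) {
        starts <- seq.int(1L, fd[ax] - w[ax] + 1L, by = g$step[ax])
        expect_identical(g$n[ax], length(starts))
      }
      # windows stay inside the frame (half-open extents)
      expect_lte(max(g$starts_ax) + w[1] - 1L, fd[1])
      expect_lte(max(g$starts_lat) + w[2] - 1L, fd[2])
    }
  })
})

test_that("segmentation keeps exactly the windows whose centre is in the selected wall", {
  ph <- phantom_config(n_cycles = 1, n_lines = 12,
                       scatterer_density_mm2 = 300, seed = 6)
  sim <- generate_sequence(ph, acq)
  d <- dim(sim$rf$frames)
  grid <- build_grid(d[1:2], c(70, 9), overlap = 0.9)
  vals <- matrix(0.01, grid$n[1], grid$n[2])
  el <- structure(list(values = vals, grid = grid, frame_pair = 1L),
                  class = "elastogram", sign = "compression_positive")
  near <- apply_segmentation(el, sim$truth$masks, wall = "near")
  far <- apply_segmentation(el, sim$truth$masks, wall = "far")
  expect_true(any(!is.na(near$values)))
  expect_true(any(!is.na(far$values)))
  # near and far retained sets are disjoint
  expect_false(any(!is.na(near$values) & !is.na(far$values)))

  # retained centres really sit in the wall band
  cen <- imbiomark:::grid_centers(grid)
  lab <- sim$truth$masks$labels[, , 1]
  keep <- which(!is.na(near$values), arr.ind = TRUE)
  labs <- lab[cbind(round(cen$ax[keep[, 1]]), round(cen$lat[keep[, 2]]))]
  expect_true(all(labs == mask_labels[["near_wall"]]))

  # all-background mask empties the elastogram
  bg <- wall_mask(array(0L, dim(sim$truth$masks$labels)))
  expect_true(all(is.na(apply_segmentation(el, bg, "near")$values)))
})

test_that("median filter: constants, outliers, missing values, idempotence", {
  grid <- build_grid(c(100, 40), c(10, 4), overlap = 0.5)
  mk_el <- function(v) structure(list(values = v, grid = grid,
                                      frame_pair = 1L),
                                 class = "elastogram")
  v <- matrix(0.01, grid$n[1], grid$n[2])
  expect_equal(median_filter(mk_el(v))$values, v)

  v2 <- v; v2[8, 8] <- 0.1
  f2 <- median_filter(mk_el(v2))
  expect_equal(f2$values[8, 8], 0.01)

  # missing cells stay missing; medians use available neighbours only
  v3 <- v; v3[, seq(1, ncol(v3), by = 2)] <- NA
  v3[6, 6] <- 0.05
  f3 <- median_filter(mk_el(v3))
  expect_true(all(is.na(f3$values[, seq(1, ncol(v3), by = 2)])))
  expect_equal(f3$values[6, 8], 0.01)

  # idempotent on piecewise-constant fields
  imbiomark:::with_seed(7, {
    for (i in 1:100) {
      vv <- matrix(rep(sample(c(0.005, 0.02), 2), each = 50), 10, 10)
      once <- median_filter(mk_el(vv))$values
      twice <- median_filter(mk_el(once))$values
      expect_identical(once, twice)
    }
  })
})

test_that("rendering maps sign to the diverging palette and keeps missing transparent", {
  grid <- build_grid(c(60, 30), c(10, 5), overlap = 0.5)
  v <- matrix(0.015, grid$n[1], grid$n[2])
  el <- structure(list(values = v, grid = grid, frame_pair = 1L),
                  class = "elastogram")
  img <- render_elastogram(el)
  # positive (compression) field renders in the blue half
  expect_true(mean(img[, , 3]) > mean(img[, , 1]))

  el$values <- -v
  img2 <- render_elastogram(el)
  expect_true(mean(img2[, , 1]) > mean(img2[, , 3]))

  # symmetric field: red and blue channels balance
  vs <- v; vs[, 1:ncol(vs)] <- rep(c(0.015, -0.015), length.out = length(vs))
  el$values <- matrix(vs, nrow(v), ncol(v))
  img3 <- render_elastogram(el)
  expect_lt(abs(mean(img3[, , 1]) - mean(img3[, , 3])), 0.05)

  # missing cells leave the background visible
  bg <- matrix(0.5, 60, 30)
  el$values[] <- NA
  img4 <- render_elastogram(el, bmode = bg)
  expect_equal(img4[, , 1], bg)
  expect_equal(img4[, , 2], bg)
})
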