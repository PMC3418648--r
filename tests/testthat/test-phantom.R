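acq <- acquisition_config()

test_that("scatterer generation is seeded, region-confined and Poisson-consistent", {
  ph <- phantom_config(seed = 11)
  s1 <- generate_scatterers(ph, acq)
  s2 <- generate_scatterers(ph, acq)
  expect_identical(s1, s2)

  # degenerate lumen density: everything lands in the wall bands
  s0 <- generate_scatterers(ph, acq, lumen_density_mm2 = 0)
  g <- imbiomark:::phantom_geometry(ph)
  in_near <- s0$z_um >= g$a0 & s0$z_um <= g$a1
  in_far <- s0$z_um >= g$b0 & s0$z_um <= g$b1
  expect_true(all(in_near | in_far))
  expect_gt(nrow(s0), 0)

  # count oracle: density d over area A gives dA +/- 3 sqrt(dA)
  width_mm <- ph$n_lines * acq$lateral_pitch_um / 1e3
  area <- 2 * ph$wall_thickness_um / 1e3 * width_mm +
    ph$lumen_diameter_um / 1e3 * width_mm
  expected <- ph$scatterer_density_mm2 * area
  expect_lt(abs(nrow(s1) - expected), 3 * sqrt(expected))

  # wall amplitudes carry the echogenicity ratio
  expect_gt(sd(s1$amp[s1$region != "lumen"]) / sd(s1$amp[s1$region == "lumen"]),
            ph$wall_to_lumen_ratio / 2)
})

test_that("deformation is exact: identity at zero strain, linear in thickness, analytic pair strain", {
  ph <- phantom_config(wall_thickness_um = 500, lumen_diameter_um = 800,
                       seed = 5)
  sc <- generate_scatterers(ph, acq)
  d0 <- deform_scatterers(sc, 0, ph, acq)
  expect_equal(d0$z_um, sc$z_um)

  # boundary-to-boundary displacement = strain x thickness
  g <- imbiomark:::phantom_geometry(ph)
  probe <- data.frame(z_um = c(g$a0, g$a1), x_um = c(0, 0), amp = c(1, 1),
                      region = "near_wall")
  phs <- seq(0.05, 0.95, by = 0.05)
  eps <- wall_compression(phs, ph, acq)
  k <- which.min(abs(eps - 0.02))
  d <- deform_scatterers(probe, phs[k], ph, acq)
  expect_equal(diff(d$z_um), 500 * (1 - eps[k]), tolerance = 1e-12)

  # finite-difference strain between nearby phases matches the analytic rate
  p1 <- 0.2; dlt <- 1e-4
  e1 <- wall_compression(p1, ph, acq); e2 <- wall_compression(p1 + dlt, ph, acq)
  a <- deform_scatterers(probe, p1, ph, acq)
  b <- deform_scatterers(probe, p1 + dlt, ph, acq)
  fd <- (diff(a$z_um) - diff(b$z_um)) / diff(a$z_um)
  expect_equal(fd, (e2 - e1) / (1 - e1), tolerance = 1e-9)
  A <- imbiomark:::cumulative_amplitude(ph, acq)
  analytic_rate <- A * pi * sin(2 * pi * p1) * dlt / (1 - e1)
  expect_lt(abs(fd - analytic_rate), 1e-6)
})

test_that("RF rendering is linear with a localized envelope peak", {
  expect_equal(render_rf_frame(data.frame(z_um = numeric(0),
                                          x_um = numeric(0),
                                          amp = numeric(0)),
                               acq, c(64, 8)),
               matrix(0, 64, 8))

  dz <- axial_spacing_um(acq)
  one <- data.frame(z_um = 100.3 * dz, x_um = 4 * acq$lateral_pitch_um,
                    amp = 1, region = "wall")
  fr <- render_rf_frame(one, acq, c(200, 9))
  env <- imbiomark:::rf_envelope(fr)
  peak <- which(env == max(env), arr.ind = TRUE)[1, ]
  expect_lte(abs(peak[1] - 101.3), 1)   # 1-based row of a 0-based position
  expect_equal(peak[[2]], 5)

  sc <- speckle_frame(3, nz = 120, nx = 8)$scatterers
  f1 <- render_rf_frame(sc, acq, c(120, 8))
  sc2 <- sc; sc2$amp <- 2 * sc2$amp
  expect_equal(render_rf_frame(sc2, acq, c(120, 8)), 2 * f1)
})

test_that("B-mode conversion: analytic envelope, floor clipping, dB gain", {
  n <- 256
  tone <- matrix(cos(2 * pi * acq$center_frequency / acq$sampling_frequency *
                       (0:(n - 1))), n, 4)
  env <- imbiomark:::rf_envelope(tone)
  expect_true(all(abs(env[20:(n - 20), ] - 1) < 0.05))

  expect_equal(render_bmode(matrix(0, 32, 4)), matrix(0, 32, 4))

  fr <- speckle_frame(9, nz = 128, nx = 6)$frame
  db1 <- render_bmode(fr, normalize = FALSE)
  db2 <- render_bmode(10 * fr, normalize = FALSE)
  expect_equal(db2 - db1, matrix(20, 128, 6), tolerance = 1e-9)
})

test_that("sequence generation: frame arithmetic, determinism, ground-truth consistency", {
  ph360 <- phantom_config(heart_rate_bpm = 360, n_cycles = 7, n_lines = 8,
                          scatterer_density_mm2 = 200, seed = 2)
  expect_identical(phantom_n_frames(ph360, acq), 70L)

  ph0 <- phantom_config(peak_axial_strain = 0, n_cycles = 2, n_lines = 8,
                        scatterer_density_mm2 = 200, seed = 2)
  sim0 <- generate_sequence(ph0, acq)
  expect_true(all(sim0$truth$pair_strain == 0))

  ph <- phantom_config(n_cycles = 2, n_lines = 8, scatterer_density_mm2 = 500,
                       seed = 8)
  a <- generate_sequence(ph, acq)
  b <- generate_sequence(ph, acq)
  expect_identical(a$rf$frames, b$rf$frames)
  expect_identical(a$truth, b$truth)

  # configured per-pair peak is attained exactly
  expect_equal(max(abs(a$truth$pair_strain)), ph$peak_axial_strain,
               tolerance = 1e-9)

  # exported strain equals finite differences of the analytic displacement
  g <- imbiomark:::phantom_geometry(ph)
  probe <- data.frame(z_um = c(g$a0, g$a1), x_um = c(0, 0), amp = c(1, 1),
                      region = "near_wall")
  n <- phantom_n_frames(ph, acq)
  h <- vapply(seq_len(n), function(k)
    diff(deform_scatterers(probe, a$truth$phase[k], ph, acq)$z_um),
    numeric(1))
  fd <- (h[-n] - h[-1]) / h[-n]
  expect_equal(fd, a$truth$pair_strain, tolerance = 1e-6)

  # masks label the wall bands at every frame
  lab1 <- a$truth$masks$labels[, 1, 1]
  expect_setequal(unique(lab1), c(0L, 1L, 2L, 3L))
})

test_that("cycle arithmetic at 351 bpm gives 10-11 frame peak spacing and periodic truth", {
  ph <- phantom_config(n_lines = 8, scatterer_density_mm2 = 200, seed = 4)
  sim <- generate_sequence(ph, acq)
  s <- sim$truth$pair_strain
  pk <- which(s >= stats::quantile(s, 0.9) &
                s >= c(-Inf, s[-length(s)]) & s > c(s[-1], -Inf))
  expect_true(all(diff(pk) %in% c(10L, 11L)))

  a <- acf(s, lag.max = 25, plot = FALSE)$acf[-1]
  per <- which.max(a[-1]) + 1L
  expect_lte(abs(per - 60 * acq$frame_rate / ph$heart_rate_bpm), 1)
})
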