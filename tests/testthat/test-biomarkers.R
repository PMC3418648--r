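# triangle-wave curve with prescribed per-cycle peak and trough magnitudes
triangle_curve <- function(peaks_pct, troughs_pct, period = 10) {
  y <- numeric(0)
  for (i in seq_along(peaks_pct)) {
    q <- period / 4
    y <- c(y,
           seq(0, peaks_pct[i], length.out = q + 1)[-1],
           seq(peaks_pct[i], 0, length.out = q + 1)[-1],
           seq(0, -troughs_pct[i], length.out = q + 1)[-1],
           seq(-troughs_pct[i], 0, length.out = q + 1)[-1])
  }
  curve_from_series(y)
}

test_that("MAS curves average the ROI and flag gaps", {
  vals <- array(0.5, c(8, 12, 6))
  st <- stack_from_values(vals)
  cur <- mas_curve(st, roi = list(ax = 2:6, lat = 2:10))
  expect_equal(cur$strain_pct, rep(50, 6))

  # 1x1 ROI reproduces the cell series
  series <- sin(1:6)
  vals2 <- vals; vals2[3, 4, ] <- series
  st2 <- stack_from_values(vals2)
  cur2 <- mas_curve(st2, roi = list(ax = 3, lat = 4))
  expect_equal(cur2$strain_pct, 100 * series)

  # fully-missing frame pair is a gap
  vals3 <- vals; vals3[, , 4] <- NA
  cur3 <- mas_curve(stack_from_values(vals3), roi = list(ax = 1:8, lat = 1:12))
  expect_identical(cur3$gaps, 4L)

  # automatic placement centres on the strongest cell
  vals4 <- array(0.001, c(8, 12, 6))
  vals4[5, 7, ] <- 0.03
  cur4 <- mas_curve(stack_from_values(vals4), roi_size = c(3, 5))
  expect_true(5 %in% cur4$roi$ax && 7 %in% cur4$roi$lat)
})

test_that("cycle detection finds sine maxima, honours ECG gating, rejects flat curves", {
  per <- 11.4
  y <- 2 + 1.5 * sin(2 * pi * (0:79) / per)
  cy <- detect_cycles(curve_from_series(y))
  true_max <- (per / 4 + 1) + per * (0:6)
  expect_equal(length(cy$peaks), 7)
  expect_true(all(abs(cy$peaks - true_max) <= 1))
  expect_lt(abs(cy$period - per), 0.5)
  # peaks and troughs strictly interleave
  both <- c(cy$peaks, cy$troughs)
  lab <- c(rep(1, length(cy$peaks)), rep(2, length(cy$troughs)))
  expect_true(all(diff(lab[order(both)]) != 0))

  ecg <- rep(0, 80); ecg[seq(3, 80, by = 11)] <- 1
  cye <- detect_cycles(curve_from_series(y), ecg = ecg)
  expect_equal(length(cye$peaks), length(seq(3, 80, by = 11)) - 1)

  expect_error(detect_cycles(curve_from_series(rep(1, 50))), "constant")

  # known heart rate can replace the autocorrelation estimate
  cyr <- detect_cycles(curve_from_series(y), expected_rate = 60 * 60 / per,
                       frame_rate = 60)
  expect_equal(length(cyr$peaks), 7)
})

test_that("PSS/PDS average the central cycles and respect the sign convention", {
  cur <- triangle_curve(peaks_pct = c(1.8, 2.0, 2.2, 2.1, 1.9),
                        troughs_pct = c(1.5, 1.6, 1.7, 1.8, 1.4), period = 12)
  cy <- detect_cycles(cur)
  expect_equal(length(cy$peaks), 5)
  sm <- summarize_stiffness(cur, cy, mode = "peak", subject = "r1",
                            side = "L")
  expect_equal(sm$pss, mean(c(2.0, 2.2, 2.1)), tolerance = 1e-6)
  expect_equal(sm$pds, mean(c(1.6, 1.7, 1.8)), tolerance = 1e-6)
  expect_identical(sm$n_cycles_used, 3L)
  expect_error(summarize_stiffness(cur, cy, n_cycles = 6), "6 required")

  # sign flip swaps the roles of peaks and troughs
  flip <- curve_from_series(-cur$strain_pct)
  smf <- summarize_stiffness(flip, detect_cycles(flip), mode = "peak")
  expect_equal(smf$pss, sm$pds, tolerance = 1e-6)
  expect_equal(smf$pds, sm$pss, tolerance = 1e-6)
})

test_that("MSS/MDS of a symmetric sine equal 2a/pi and mean strain combines them", {
  a <- 3; per <- 20
  cur <- curve_from_series(a * sin(2 * pi * (0:119) / per))
  sm <- summarize_stiffness(cur, mode = "mean")
  expect_equal(sm$mss, 2 * a / pi, tolerance = 0.05)
  expect_equal(sm$mds, -2 * a / pi, tolerance = 0.05)
  expect_equal(sm$mean_strain, (abs(sm$mss) + abs(sm$mds)) / 2)
})

test_that("pooling schemes multiply the population as the factor product", {
  rats <- expand.grid(subject = paste0("r", 1:5), side = c("L", "R"),
                      stringsAsFactors = FALSE)
  rats$group <- "15wk"
  rats$pss <- 12 + seq_len(nrow(rats)) / 10
  rats$pds <- 11 + seq_len(nrow(rats)) / 10
  pooled <- pool_measurements(rats, "rat_side_phase")
  expect_identical(nrow(pooled), 20L)
  expect_identical(attr(pooled, "multiplier"), 4L)
  expect_setequal(unique(pooled$phase), c("systole", "diastole"))

  hum <- expand.grid(subject = paste0("s", 1:7), recording = 1:3,
                     wall = c("near", "far"), stringsAsFactors = FALSE)
  hum$group <- ifelse(hum$subject %in% c("s1", "s2"), "KD", "KD-free")
  hum$mean_strain <- 3 + seq_len(nrow(hum)) / 100
  pooledh <- pool_measurements(hum, "human_wall_triplicate")
  expect_identical(nrow(pooledh), 42L)
  expect_identical(attr(pooledh, "multiplier"), 6L)
  expect_identical(sum(pooledh$subject == "s1"), 6L)

  one <- pool_measurements(rats, "none")
  expect_identical(attr(one, "multiplier"), 1L)
  expect_identical(nrow(one), nrow(rats))
})
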