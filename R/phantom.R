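#' Pulsating-vessel phantom configuration
#'
#' Describes a synthetic longitudinal vessel section: two echogenic wall
#' bands around a hypoechoic lumen, insonified from above, whose walls
#' undergo a prescribed periodic axial compression over `n_cycles` cardiac
#' cycles.  The phantom exists so that every downstream stage (tracking,
#' elastograms, biomarkers) can be validated against analytic ground truth.
#'
#' `peak_axial_strain` is the peak *per-frame-pair* wall strain (the
#' quantity the tracker estimates and the MAS curve plots).  The cumulative
#' through-thickness compression follows a raised-cosine over the cycle; its
#' amplitude is solved internally so the discrete frame-to-frame strain
#' series attains exactly the configured peak.
#'
#' @param wall_thickness_um wall band thickness, micrometres.  Small-rodent
#'   carotid walls are on the order of 150 um.
#' @param lumen_diameter_um lumen (anechoic gap) diameter, micrometres.
#' @param scatterer_density_mm2 scatterers per mm^2 (both walls and lumen);
#'   the default gives fully developed speckle (>~10 scatterers per
#'   resolution cell at 40 MHz).
#' @param wall_to_lumen_ratio wall : lumen scatterer amplitude ratio (> 1;
#'   10 corresponds to a ~-20 dB hypoechoic lumen).
#' @param peak_axial_strain peak per-frame-pair axial strain in the wall
#'   (fraction, in (0, 0.2)); compression positive.
#' @param heart_rate_bpm cardiac frequency, beats/min.
#' @param n_cycles number of cardiac cycles recorded.
#' @param noise_level additive white-noise standard deviation relative to
#'   the RF signal RMS.
#' @param n_lines number of scan lines (lateral image width).
#' @param margin_um quiet margin above the near wall and below the far
#'   wall, micrometres.
#' @param image_depth_um optional total image depth; defaults to the
#'   geometry plus margins, and it is an error to request less.
#' @param seed integer seed making the phantom fully reproducible.
#'
#' @return Object of class `phantom_config`.
#' @export
phantom_config <- function(wall_thickness_um = 150,
                           lumen_diameter_um = 900,
                           scatterer_density_mm2 = 5000,
                           wall_to_lumen_ratio = 10,
                           peak_axial_strain = 0.02,
                           heart_rate_bpm = 351,
                           n_cycles = 7L,
                           noise_level = 0.1,
                           n_lines = 64L,
                           margin_um = 100,
                           image_depth_um = NULL,
                           seed = 1L) {
  stopifnot(wall_thickness_um > 0, lumen_diameter_um > 0,
            scatterer_density_mm2 >= 0, wall_to_lumen_ratio > 1,
            heart_rate_bpm > 0, noise_level >= 0, n_lines >= 4,
            margin_um >= 0)
  if (!(peak_axial_strain >= 0 && peak_axial_strain < 0.2))
    stop_fmt("phantom_config: peak_axial_strain must be in [0, 0.2)")
  if (n_cycles < 1) stop_fmt("phantom_config: n_cycles must be >= 1")
  need <- 2 * margin_um + 2 * wall_thickness_um + lumen_diameter_um
  if (is.null(image_depth_um)) image_depth_um <- need
  if (image_depth_um < need)
    stop_fmt("phantom_config: geometry needs %.0f um depth but image_depth_um = %.0f",
             need, image_depth_um)
  structure(list(wall_thickness_um = wall_thickness_um,
                 lumen_diameter_um = lumen_diameter_um,
                 scatterer_density_mm2 = scatterer_density_mm2,
                 wall_to_lumen_ratio = wall_to_lumen_ratio,
                 peak_axial_strain = peak_axial_strain,
                 heart_rate_bpm = heart_rate_bpm,
                 n_cycles = as.integer(n_cycles),
                 noise_level = noise_level,
                 n_lines = as.integer(n_lines),
                 margin_um = margin_um,
                 image_depth_um = image_depth_um,
                 seed = as.integer(seed)),
            class = "phantom_config")
}

# axial geometry in micrometres: near wall [a0, a1], lumen (a1, b0), far
# wall [b0, b1]; outer edges a0, b1 are anchored during the cycle
phantom_geometry <- function(phantom) {
  a0 <- phantom$margin_um
  a1 <- a0 + phantom$wall_thickness_um
  b0 <- a1 + phantom$lumen_diameter_um
  b1 <- b0 + phantom$wall_thickness_um
  list(a0 = a0, a1 = a1, b0 = b0, b1 = b1,
       depth_um = phantom$image_depth_um)
}

#' Frame count and cardiac phase of a phantom recording
#'
#' `phantom_n_frames` is `ceiling(n_cycles * frame_rate * 60 / heart_rate)`;
#' `phantom_phase` gives each frame's cardiac phase in `[0, 1)`.
#'
#' @param phantom a [phantom_config()].
#' @param acq an [acquisition_config()].
#' @return Integer frame count / numeric phase vector.
#' @export
phantom_n_frames <- function(phantom, acq) {
  n <- as.integer(ceiling(phantom$n_cycles * acq$frame_rate * 60 /
                            phantom$heart_rate_bpm))
  if (n < 2)
    stop_fmt("phantom_n_frames: configuration yields %d frame(s); need >= 2", n)
  n
}

#' @rdname phantom_n_frames
#' @export
phantom_phase <- function(phantom, acq) {
  n <- phantom_n_frames(phantom, acq)
  ((seq_len(n) - 1) * phantom$heart_rate_bpm / (60 * acq$frame_rate)) %% 1
}

raised_cosine <- function(phase) (1 - cos(2 * pi * phase)) / 2

# Cumulative raised-cosine amplitude A such that the per-frame-pair strain
# series s_k = (eps_{k+1} - eps_k) / (1 - eps_k), eps = A * rc(phase),
# attains exactly the configured per-pair peak.
cumulative_amplitude <- function(phantom, acq) {
  if (phantom$peak_axial_strain == 0) return(0)
  ph <- phantom_phase(phantom, acq)
  peak_of <- function(A) {
    eps <- A * raised_cosine(ph)
    n <- length(eps)
    max(abs((eps[-1] - eps[-n]) / (1 - eps[-n])))
  }
  f <- function(A) peak_of(A) - phantom$peak_axial_strain
  if (f(0.8) < 0)
    stop_fmt("cumulative_amplitude: configured peak strain is unreachable (cumulative compression would exceed 80%%)")
  stats::uniroot(f, c(1e-9, 0.8), tol = 1e-12)$root
}

#' Cumulative wall compression at a cardiac phase
#'
#' The through-thickness compression fraction `eps(phase)` applied to both
#' wall bands: a raised cosine over the cycle (0 at end-diastole, maximal at
#' mid-cycle), with amplitude derived from `peak_axial_strain` (see
#' [phantom_config()]).
#'
#' @param phase cardiac phase(s), any real (interpreted modulo 1).
#' @inheritParams phantom_n_frames
#' @return Compression fraction(s) in `[0, 1)`.
#' @export
wall_compression <- function(phase, phantom, acq) {
  cumulative_amplitude(phantom, acq) * raised_cosine(phase)
}

#' Generate phantom scatterers
#'
#' Point scatterers uniformly distributed in the wall bands and the lumen,
#' with Gaussian amplitudes; wall amplitudes are scaled by the
#' wall-to-lumen echogenicity ratio.  Reproducible from the phantom seed.
#'
#' @inheritParams phantom_n_frames
#' @param lumen_density_mm2 optional override of the lumen scatterer
#'   density (default: same as the walls).
#' @return A data.frame with columns `z_um`, `x_um`, `amp`, `region`
#'   (`"near_wall"`, `"far_wall"` or `"lumen"`).
#' @export
generate_scatterers <- function(phantom, acq, lumen_density_mm2 = NULL) {
  stopifnot(inherits(phantom, "phantom_config"), inherits(acq, "acq_config"))
  if (is.null(lumen_density_mm2))
    lumen_density_mm2 <- phantom$scatterer_density_mm2
  g <- phantom_geometry(phantom)
  width_um <- phantom$n_lines * acq$lateral_pitch_um
  regions <- list(
    near_wall = list(z0 = g$a0, z1 = g$a1,
                     d = phantom$scatterer_density_mm2,
                     amp = phantom$wall_to_lumen_ratio),
    far_wall = list(z0 = g$b0, z1 = g$b1,
                    d = phantom$scatterer_density_mm2,
                    amp = phantom$wall_to_lumen_ratio),
    lumen = list(z0 = g$a1, z1 = g$b0, d = lumen_density_mm2, amp = 1))
  with_seed(phantom$seed, {
    out <- lapply(names(regions), function(nm) {
      r <- regions[[nm]]
      area_mm2 <- (r$z1 - r$z0) * width_um / 1e6
      n <- rpois(1, r$d * area_mm2)
      if (n == 0)
        return(data.frame(z_um = numeric(0), x_um = numeric(0),
                          amp = numeric(0), region = character(0)))
      data.frame(z_um = runif(n, r$z0, r$z1),
                 x_um = runif(n, 0, width_um),
                 amp = rnorm(n) * r$amp,
                 region = nm)
    })
    do.call(rbind, out)
  })
}

#' Displace scatterers to a cardiac phase
#'
#' The analytic motion model: both wall bands carry a uniform
#' through-thickness axial compression `eps(phase)` anchored at their outer
#' edges, so the lumen dilates symmetrically while the outer boundaries stay
#' fixed; lumen scatterers follow the (zero) rigid motion of the lumen
#' centre.  The displacement field is exact and differentiable, so the
#' per-frame-pair ground-truth strain is analytic.
#'
#' @param scatterers output of [generate_scatterers()] (reference, phase 0).
#' @param phase cardiac phase in `[0, 1)` (any real accepted, modulo 1).
#' @inheritParams phantom_n_frames
#' @return The scatterer data.frame with displaced `z_um`.
#' @export
deform_scatterers <- function(scatterers, phase, phantom, acq) {
  eps <- wall_compression(phase, phantom, acq)
  g <- phantom_geometry(phantom)
  z <- scatterers$z_um
  near <- scatterers$region == "near_wall"
  far <- scatterers$region == "far_wall"
  z[near] <- g$a0 + (z[near] - g$a0) * (1 - eps)
  z[far] <- g$b1 - (g$b1 - z[far]) * (1 - eps)
  out <- scatterers
  out$z_um <- z
  out
}

# axial carrier (rad/sample) and Gaussian PSF widths in sample units
psf_params <- function(acq) {
  dz_um <- axial_spacing_um(acq)
  k_ax <- 2 * pi * acq$center_frequency / acq$sampling_frequency
  df <- acq$fractional_bandwidth * acq$center_frequency      # -6 dB width, Hz
  sig_f <- df / (2 * sqrt(2 * log(2)))
  sig_t <- 1 / (2 * pi * sig_f)
  sig_z_um <- acq$speed_of_sound * sig_t / 2 * 1e6
  list(k_ax = k_ax,
       sig_z = sig_z_um / dz_um,
       sig_x = acq$lateral_beamwidth_um / (2 * sqrt(2 * log(2))) /
         acq$lateral_pitch_um)
}

#' Render an RF frame from scatterers
#'
#' Linear superposition of a separable point-spread function per scatterer:
#' axially a Gaussian-windowed cosine at the probe centre frequency (width
#' set by the fractional bandwidth), laterally a Gaussian of the configured
#' -6 dB beam width; truncated at 4 sigma.  Optional additive white noise
#' relative to the frame RMS.
#'
#' @param scatterers a scatterer data.frame (possibly deformed).
#' @param acq an [acquisition_config()].
#' @param dim integer c(n_axial_samples, n_lines).
#' @param noise_level additive white-noise sd relative to frame RMS.
#' @return Numeric matrix `[axial, lateral]`.
#' @export
render_rf_frame <- function(scatterers, acq, dim, noise_level = 0) {
  stopifnot(length(dim) == 2L, all(dim >= 4))
  p <- psf_params(acq)
  dz_um <- axial_spacing_um(acq)
  fr <- render_rf_cpp(scatterers$z_um / dz_um,
                      scatterers$x_um / acq$lateral_pitch_um,
                      if (nrow(scatterers)) scatterers$amp else numeric(0),
                      as.integer(dim[1]), as.integer(dim[2]),
                      p$k_ax, p$sig_z, p$sig_x, 4 * p$sig_z, 4 * p$sig_x)
  if (noise_level > 0) {
    rms <- sqrt(mean(fr^2))
    fr <- fr + rnorm(length(fr), sd = noise_level * rms)
  }
  fr
}

# analytic-signal envelope per column (axial direction)
rf_envelope <- function(frame) {
  n <- nrow(frame)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  Mod(mvfft(mvfft(frame) * h, inverse = TRUE)) / n
}

#' B-mode conversion of an RF frame
#'
#' Envelope detection by the analytic-signal magnitude along the axial
#' direction, then log compression over `dynamic_range_db` and (by default)
#' normalization to `[0, 1]` with the frame maximum at 1.
#'
#' @param frame RF matrix `[axial, lateral]`.
#' @param dynamic_range_db displayed dynamic range, dB.
#' @param normalize if `FALSE`, return unnormalized envelope amplitude in
#'   dB (`20*log10(envelope)`), useful for gain checks.
#' @return Matrix of the same shape.
#' @export
render_bmode <- function(frame, dynamic_range_db = 40, normalize = TRUE) {
  env <- rf_envelope(frame)
  if (!normalize) return(20 * log10(pmax(env, .Machine$double.xmin)))
  m <- max(env)
  if (m == 0) return(array(0, dim(frame)))
  db <- 20 * log10(pmax(env / m, 10^(-dynamic_range_db / 20 - 2)))
  out <- (pmax(db, -dynamic_range_db) + dynamic_range_db) / dynamic_range_db
  array(out, dim(frame))
}

#' Generate a full phantom sequence with ground truth
#'
#' Renders `ceiling(n_cycles * frame_rate * 60 / heart_rate)` RF frames of
#' the pulsating vessel, the matching B-mode sequence, and the exported
#' ground truth: per-frame-pair wall strain (compression positive),
#' per-frame cardiac phase, and per-frame wall label masks.  Deterministic
#' from the phantom seed.
#'
#' @inheritParams phantom_n_frames
#' @return A list of class `phantom_sequence` with elements `rf`, `bmode`
#'   (both [rf_sequence()]), `truth` (list: `pair_strain`, `phase`, `masks`)
#'   and the two configs.
#' @export
generate_sequence <- function(phantom, acq) {
  stopifnot(inherits(phantom, "phantom_config"), inherits(acq, "acq_config"))
  n <- phantom_n_frames(phantom, acq)
  dz_um <- axial_spacing_um(acq)
  nz <- as.integer(round(phantom$image_depth_um / dz_um))
  nx <- phantom$n_lines
  ph_wrapped <- phantom_phase(phantom, acq)
  ph_unwrapped <- (seq_len(n) - 1) * phantom$heart_rate_bpm /
    (60 * acq$frame_rate)
  A <- cumulative_amplitude(phantom, acq)
  eps <- A * raised_cosine(ph_unwrapped)
  scat <- generate_scatterers(phantom, acq)

  frames <- array(0, c(nz, nx, n))
  for (k in seq_len(n)) {
    d <- deform_scatterers(scat, ph_wrapped[k], phantom, acq)
    frames[, , k] <- render_rf_frame(d, acq, c(nz, nx))
  }
  if (phantom$noise_level > 0) {
    rms <- sqrt(mean(frames^2))
    frames <- frames + with_seed((phantom$seed + 1L) %% .Machine$integer.max,
                                 array(rnorm(length(frames),
                                             sd = phantom$noise_level * rms),
                                       dim(frames)))
  }
  rf <- rf_sequence(frames, acq, "RF")
  bm <- array(0, dim(frames))
  for (k in seq_len(n)) bm[, , k] <- render_bmode(frames[, , k])
  bmode <- rf_sequence(bm, acq, "BMODE")

  pair_strain <- (eps[-1] - eps[-n]) / (1 - eps[-n])
  g <- phantom_geometry(phantom)
  z_um <- (seq_len(nz) - 1) * dz_um
  labels <- array(0L, c(nz, nx, n))
  for (k in seq_len(n)) {
    a1k <- g$a0 + phantom$wall_thickness_um * (1 - eps[k])
    b0k <- g$b1 - phantom$wall_thickness_um * (1 - eps[k])
    lab <- integer(nz)
    lab[z_um >= g$a0 & z_um <= a1k] <- mask_labels[["near_wall"]]
    lab[z_um > a1k & z_um < b0k] <- mask_labels[["lumen"]]
    lab[z_um >= b0k & z_um <= g$b1] <- mask_labels[["far_wall"]]
    labels[, , k] <- matrix(lab, nz, nx)
  }
  structure(list(rf = rf, bmode = bmode,
                 truth = list(pair_strain = pair_strain,
                              phase = ph_wrapped,
                              masks = wall_mask(labels)),
                 phantom = phantom, acq = acq),
            class = "phantom_sequence")
}

#' @export
print.phantom_sequence <- function(x, ...) {
  d <- dim(x$rf$frames)
  cat(sprintf("<phantom_sequence> %d frames of %d x %d, %d cycle(s), peak pair strain %.3f%%\n",
              d[3], d[1], d[2], x$phantom$n_cycles,
              100 * x$phantom$peak_axial_strain))
  invisible(x)
}
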