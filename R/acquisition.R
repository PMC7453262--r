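#' Illumination models
#'
#' Spectral power distributions (SPD, on the fine 1-nm grid, max-normalized)
#' for the three light sources used with the laparoscope: a combined
#' visible + near-infrared LED, a xenon arc and a halogen lamp
#' (blackbody-like, rising into the NIR). The spatial model is a radially
#' symmetric Gaussian illumination spot whose relative intensity is 1 at the
#' center and 0.5 at `half_intensity_radius_px` (default 150 px, in native
#' 640 x 480 output-pixel units), plus a power-law falloff
#' `(d_ref / d)^distance_exponent` with the working distance (default
#' exponent 1.8, close to the inverse-square law of a point source).
#'
#' @param name One of `"led_nir"`, `"xenon"`, `"halogen"`.
#' @param half_intensity_radius_px Spot radius at 50% relative intensity.
#' @param distance_exponent Power-law exponent of the distance falloff.
#' @param power_fraction Relative drive power in `(0, 1]`.
#' @param spd Optional custom SPD (length 501, non-negative) overriding the
#'   named shape.
#' @return A `light_source` object.
#' @export
light_source <- function(name = c("led_nir", "xenon", "halogen"),
                         half_intensity_radius_px = 150,
                         distance_exponent = 1.8,
                         power_fraction = 1,
                         spd = NULL) {
  name <- match.arg(name)
  lam <- fine_wavelengths()
  if (is.null(spd)) {
    spd <- switch(name,
      led_nir = 0.05 + 0.85 * exp(-((lam - 560) / 50)^2) +
        0.90 * exp(-((lam - 740) / 70)^2),
      xenon = 0.75 + 0.08 * exp(-((lam - 820) / 12)^2) +
        0.06 * exp(-((lam - 880) / 15)^2) + 0.05 * exp(-((lam - 920) / 12)^2),
      halogen = {
        # blackbody-like shape at 3200 K (relative spectral radiance)
        b <- lam^-5 / (exp(1.4388e7 / (lam * 3200)) - 1)
        b
      })
  }
  if (any(spd < 0) || length(spd) != length(lam))
    stop("SPD must be non-negative on the fine grid", call. = FALSE)
  spd <- spd / max(spd)
  stopifnot(power_fraction > 0, power_fraction <= 1,
            half_intensity_radius_px > 0)
  structure(list(name = name, spd = spd,
                 half_intensity_radius_px = half_intensity_radius_px,
                 distance_exponent = distance_exponent,
                 power_fraction = power_fraction),
            class = "light_source")
}

#' Gaussian illumination spot profile
#'
#' Relative intensity at pixel radius `r_px` from the spot center: 1 at the
#' center, monotone non-increasing, 0.5 at `half_intensity_radius_px`.
#' @param r_px Radius in output pixels.
#' @param half_intensity_radius_px Half-intensity radius.
#' @export
spot_profile <- function(r_px, half_intensity_radius_px = 150) {
  exp(-log(2) * (r_px / half_intensity_radius_px)^2)
}

#' Monochrome sensor model
#'
#' Relative quantum efficiency on the fine grid (smooth hump peaking in the
#' red) with a sinusoidal etalon-like ripple above 800 nm, a black level,
#' additive Gaussian read noise, full-scale clipping, the 140-fps line
#' readout, and the true pixel-index-to-wavelength map of the spectrograph
#' (ascending-power polynomial) that the krypton calibration estimates.
#'
#' @param ripple Enable the QE ripple above 800 nm.
#' @param ripple_amplitude,ripple_period_nm Ripple modulation depth and
#'   period.
#' @param read_noise_sigma Additive noise sigma in counts.
#' @param black_level Dark offset in counts.
#' @param full_scale Saturation level in counts.
#' @param frame_rate Line-frame rate in frames per second.
#' @param exposure_scale Counts per unit spectral radiance (folds exposure
#'   time and gain, which the instrument keeps fixed across measurements).
#' @param spectral_map_coeffs True pixel-to-wavelength polynomial (nm).
#' @return A `sensor_model` object with the evaluated `qe` curve.
#' @export
sensor_model <- function(ripple = TRUE, ripple_amplitude = 0.08,
                         ripple_period_nm = 25, read_noise_sigma = 3,
                         black_level = 64, full_scale = 4095,
                         frame_rate = 140, exposure_scale = 3000,
                         spectral_map_coeffs = c(500, 0.63, 1e-5)) {
  lam <- fine_wavelengths()
  qe <- 0.8 * exp(-((lam - 650) / 400)^2)
  if (ripple) {
    gate <- 1 / (1 + exp(-(lam - 800) / 5))
    qe <- qe * (1 + ripple_amplitude * gate * sin(2 * pi * (lam - 800) / ripple_period_nm))
  }
  stopifnot(all(qe > 0), all(qe <= 1))
  structure(list(qe = qe, ripple = ripple, read_noise_sigma = read_noise_sigma,
                 black_level = black_level, full_scale = full_scale,
                 frame_rate = frame_rate, exposure_scale = exposure_scale,
                 spectral_map_coeffs = spectral_map_coeffs),
            class = "sensor_model")
}

#' Acquisition configuration
#'
#' Geometry, light source, sensor and calibration for one simulated
#' pushbroom acquisition. Defaults reproduce the device: 640 lines at
#' 140 fps, 960 x 780 (spatial x spectral) raw readout binned 2 x 5 to
#' 480 x 100, field of view 55 x 48 mm^2 at the 5-cm reference distance and
#' scaling linearly with distance.
#'
#' @param n_lines Number of scan lines.
#' @param distance_cm Working distance (5--10 cm on the device).
#' @param light A [light_source()].
#' @param sensor A [sensor_model()].
#' @param cal A `spectral_cal`; default [default_calibration()].
#' @param seed Integer seed; every stochastic frame render derives its own
#'   substream from it, so scans are reproducible frame-by-frame.
#' @param psf Optional [psf_model()] scene blur.
#' @param scan_window_mm Optional `c(x0, x1)` in mm restricting the scanned
#'   along-scan range (the default covers the full field of view); the
#'   across-scan axis always spans the field of view.
#' @param n_dark Dark frames averaged by [acquire_references()].
#' @param fov_ref_mm Field of view `c(x, y)` in mm at `ref_distance_cm`.
#' @param ref_distance_cm Reference distance the FOV is anchored at.
#' @return An `acquisition_config`.
#' @export
acquisition_config <- function(n_lines = 640L, distance_cm = 5,
                               light = light_source("led_nir"),
                               sensor = sensor_model(),
                               cal = default_calibration(),
                               seed = 1L, psf = NULL,
                               scan_window_mm = NULL, n_dark = 16L,
                               fov_ref_mm = c(55, 48), ref_distance_cm = 5) {
  stopifnot(n_lines >= 1, distance_cm > 0)
  structure(list(n_lines = as.integer(n_lines), distance_cm = distance_cm,
                 light = light, sensor = sensor, cal = cal,
                 seed = as.integer(seed), psf = psf,
                 scan_window_mm = scan_window_mm, n_dark = as.integer(n_dark),
                 fov_ref_mm = fov_ref_mm, ref_distance_cm = ref_distance_cm,
                 n_spatial = 960L, n_spectral = 780L,
                 spatial_factor = 2L, spectral_factor = 5L),
            class = "acquisition_config")
}

#' Field of view at the configured distance (linear scaling from the anchor)
#' @param cfg An [acquisition_config()].
#' @return `c(x, y)` extent in mm.
#' @export
fov_mm <- function(cfg) cfg$fov_ref_mm * cfg$distance_cm / cfg$ref_distance_cm

scan_window <- function(cfg) {
  if (!is.null(cfg$scan_window_mm)) cfg$scan_window_mm else c(0, fov_mm(cfg)[1])
}

# along-scan position (mm) of 0-based line index
line_x_mm <- function(cfg, line) {
  w <- scan_window(cfg)
  w[1] + (line + 0.5) * (w[2] - w[1]) / cfg$n_lines
}

# across-scan positions (mm) of n equally spaced samples
sample_y_mm <- function(cfg, n) {
  (seq_len(n) - 0.5) * fov_mm(cfg)[2] / n
}

# Spot radius in native output-pixel units. The illumination spot is
# centered on the slit and characterized within a frame (the device measures
# both the falloff profile and the SNR line groups at a fixed slit
# position), so the radius is the in-frame distance from the slit center
# along the spatial axis; it does not depend on the scan line.
spot_radius_px <- function(cfg, y) {
  f <- fov_mm(cfg)
  abs(y - f[2] / 2) / (f[2] / 480)
}

distance_gain <- function(cfg) {
  (cfg$ref_distance_cm / cfg$distance_cm)^cfg$light$distance_exponent
}

# per-frame RNG substream; streams: 0 = object scan, 1 = white, 2 = dark
frame_seed <- function(seed, line, stream = 0L) {
  as.integer((abs(seed) * 100003 + stream * 1009 + line) %% 2147483647)
}

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())))
  }
  set.seed(seed)
  expr
}

# precomputed render context: spectra and illumination resampled to the
# 780 sensor-pixel wavelengths
render_context <- function(scene, cfg, illum_on = TRUE) {
  lam <- fine_wavelengths()
  lam_px <- drop(outer(0:(cfg$n_spectral - 1L),
                       seq_along(cfg$sensor$spectral_map_coeffs) - 1, `^`) %*%
                   cfg$sensor$spectral_map_coeffs)
  lam_px <- pmin(pmax(lam_px, lam[1]), lam[length(lam)])
  i0 <- pmin(pmax(floor(lam_px - lam[1]) + 1L, 1L), length(lam) - 1L)
  w <- lam_px - lam[i0]
  resample <- function(s) s[, i0, drop = FALSE] * rep(1 - w, each = nrow(s)) +
    s[, i0 + 1L, drop = FALSE] * rep(w, each = nrow(s))
  spectra <- patch_spectra(scene)
  gain <- if (illum_on)
    cfg$light$spd * cfg$sensor$qe * cfg$sensor$exposure_scale *
      distance_gain(cfg) * cfg$light$power_fraction
  else rep(0, length(lam))
  list(
    s780 = resample(spectra),
    gain780 = drop(resample(rbind(gain))),
    y_raw = sample_y_mm(cfg, cfg$n_spatial),
    lam_px = lam_px
  )
}

# deterministic counts of one line frame (960 x 780), before noise/clipping
frame_deterministic <- function(scene, cfg, line, ctx) {
  x <- line_x_mm(cfg, line)
  W <- if (is.null(cfg$psf)) scene_weights(scene, x, ctx$y_raw)
       else NULL
  refl <- if (!is.null(W)) W %*% ctx$s780
          else {
            # PSF path: mix on the fine grid, then resample
            rf <- scene_reflectance(scene, x, ctx$y_raw, cfg$psf)
            lam <- fine_wavelengths()
            i0 <- pmin(pmax(floor(ctx$lam_px - lam[1]) + 1L, 1L), length(lam) - 1L)
            wv <- ctx$lam_px - lam[i0]
            rf[, i0, drop = FALSE] * rep(1 - wv, each = nrow(rf)) +
              rf[, i0 + 1L, drop = FALSE] * rep(wv, each = nrow(rf))
          }
  spot <- spot_profile(spot_radius_px(cfg, ctx$y_raw),
                       cfg$light$half_intensity_radius_px)
  counts <- refl * rep(ctx$gain780, each = nrow(refl)) * spot
  counts + cfg$sensor$black_level
}

finish_frame <- function(counts, cfg, line, stream) {
  s <- cfg$sensor
  if (s$read_noise_sigma > 0) {
    counts <- with_seed(frame_seed(cfg$seed, line, stream),
                        counts + rnorm(length(counts), 0, s$read_noise_sigma))
  }
  counts <- pmin(pmax(counts, 0), s$full_scale)
  attr(counts, "line_index") <- line
  counts
}

#' Spectral radiance reaching the sensor for one scene pixel
#'
#' Scene reflectance at the pixel times light-source SPD, spot profile at
#' the pixel's radius, distance falloff `(d_ref/d)^p` and drive power, on
#' the fine 1-nm grid. Sensor effects (QE, counts scaling, black level,
#' noise) are applied later by [render_raw_frame()].
#'
#' @param scene A [scene_spec()].
#' @param cfg An [acquisition_config()].
#' @param line 0-based line index.
#' @param sample 0-based raw spatial pixel index (0..959).
#' @return Length-501 spectrum.
#' @export
radiance_at <- function(scene, cfg, line, sample) {
  stopifnot(sample >= 0, sample < cfg$n_spatial)
  x <- line_x_mm(cfg, line)
  y <- sample_y_mm(cfg, cfg$n_spatial)[sample + 1L]
  refl <- drop(scene_reflectance(scene, x, y, cfg$psf))
  spot <- spot_profile(spot_radius_px(cfg, y),
                       cfg$light$half_intensity_radius_px)
  refl * cfg$light$spd * spot * distance_gain(cfg) * cfg$light$power_fraction
}

#' Render one raw pushbroom line frame
#'
#' Full sensor forward model for scan line `line`: fine-grid radiance per
#' spatial pixel, resampled to the 780 spectral-pixel axis through the
#' sensor's true wavelength map, multiplied by the quantum-efficiency curve,
#' scaled to counts, black level added, seeded Gaussian read noise added,
#' and clipped to `[0, full_scale]`. The noise substream is derived from
#' `(cfg$seed, line)`, so repeated renders of the same line are
#' bit-identical.
#'
#' @inheritParams radiance_at
#' @return 960 x 780 matrix of counts with attribute `line_index`.
#' @export
render_raw_frame <- function(scene, cfg, line) {
  stopifnot(line >= 0, line < cfg$n_lines)
  ctx <- render_context(scene, cfg)
  finish_frame(frame_deterministic(scene, cfg, line, ctx), cfg, line, 0L)
}

#' Simulate a full pushbroom scan
#'
#' Renders `cfg$n_lines` raw line frames in line order (the device records
#' 640 while the spectrograph traverses the image plane) together with the
#' ground-truth reflectance sampled on the binned output grid
#' (`n_lines x 480 x 100`), i.e. the scene reflectance averaged over each
#' 5-nm output channel at the binned pixel centers.
#'
#' @inheritParams radiance_at
#' @param stream Internal RNG substream selector.
#' @return List with `frames` (list of raw frames), `ground_truth`
#'   (a `reflectance_cube` whose values are absolute scene reflectance) and
#'   `cfg`.
#' @export
scan <- function(scene, cfg, stream = 0L) {
  ctx <- render_context(scene, cfg)
  n_bin <- cfg$n_spatial %/% cfg$spatial_factor
  grid <- build_wavelength_grid(500L %/% cfg$spectral_factor, 500, 1000)
  # fine -> 5-nm channel averaging (channel k covers centers 500+5k..504+5k)
  nch <- length(grid$centers)
  y_bin <- sample_y_mm(cfg, n_bin)
  frames <- vector("list", cfg$n_lines)
  gt <- array(NA_real_, c(cfg$n_lines, n_bin, nch))
  # fine-grid (1 nm) to 5-nm channel block-mean operator
  CM <- matrix(0, length(fine_wavelengths()), nch)
  CM[cbind(seq_len(5L * nch), rep(seq_len(nch), each = 5L))] <- 1 / 5
  for (l in seq_len(cfg$n_lines) - 1L) {
    frames[[l + 1L]] <- finish_frame(frame_deterministic(scene, cfg, l, ctx),
                                     cfg, l, stream)
    rf <- scene_reflectance(scene, line_x_mm(cfg, l), y_bin, cfg$psf)
    gt[l + 1L, , ] <- rf %*% CM
  }
  ground_truth <- new_hyper_cube(gt, grid,
                                 array(TRUE, dim(gt)),
                                 list(distance_cm = cfg$distance_cm,
                                      light = cfg$light$name, seed = cfg$seed,
                                      scene = scene$name),
                                 kind = "reflectance")
  list(frames = frames, ground_truth = ground_truth, cfg = cfg)
}

# process one raw frame to the binned geometry with the fused spectral
# operator (identical, up to float rounding, to map_spectral_axis + bin_frame)
process_frame <- function(frame, cfg, P) {
  x <- unclass(frame) %*% P
  rowsum(x, group = rep(seq_len(nrow(x) %/% cfg$spatial_factor),
                        each = cfg$spatial_factor)) / cfg$spatial_factor
}

#' Acquire dark and white references for a configuration
#'
#' Dark: the mean of `cfg$n_dark` frames rendered with the illumination off
#' (only black level and read noise), calibrated and binned. White: a scan
#' of the white scene at the configured distance, calibrated, binned and
#' averaged over `n_white_lines` lines to a single reference frame, which
#' balancing broadcasts across scan lines (the illumination model does not
#' vary along the scan, so the average is exact up to noise; averaging
#' suppresses the reference's own read noise).
#'
#' @param cfg An [acquisition_config()].
#' @param white_scene Scene used as white reference (default
#'   [scene_white_paper()]).
#' @param n_white_lines Lines averaged into the white reference.
#' @return A [reference_set()].
#' @export
acquire_references <- function(cfg, white_scene = scene_white_paper(),
                               n_white_lines = 64L) {
  dark_ctx <- render_context(white_scene, cfg, illum_on = FALSE)
  P <- spectral_bin_operator(cfg$cal, calibration_grid(), cfg$spectral_factor)
  dark_acc <- 0
  for (i in seq_len(cfg$n_dark)) {
    fr <- finish_frame(frame_deterministic(white_scene, cfg, 0L, dark_ctx),
                       cfg, i - 1L, 2L)
    dark_acc <- dark_acc + process_frame(fr, cfg, P)
  }
  dark <- dark_acc / cfg$n_dark
  wcfg <- cfg
  wcfg$n_lines <- as.integer(n_white_lines)
  wctx <- render_context(white_scene, wcfg)
  white_acc <- 0
  for (l in seq_len(wcfg$n_lines) - 1L) {
    fr <- finish_frame(frame_deterministic(white_scene, wcfg, l, wctx),
                       wcfg, l, 1L)
    white_acc <- white_acc + process_frame(fr, cfg, P)
  }
  reference_set(dark, white_acc / wcfg$n_lines, distance_cm = cfg$distance_cm)
}
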