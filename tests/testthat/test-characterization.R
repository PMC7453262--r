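# closed-form SNR of Eq.-(2) type for Gaussian noise: the mean absolute
# deviation of N(0, sigma) is sigma * sqrt(2/pi)
snr_gaussian_db <- function(mu, sigma) 20 * log10(mu / (sigma * sqrt(2 / pi)))

gaussian_stack <- function(mu, sigma, n_frames, nr = 30, nc = 12, seed = 1) {
  set.seed(seed)
  array(rnorm(nr * nc * n_frames, mu, sigma), c(nr, nc, n_frames))
}

test_that("the SNR map matches the Gaussian closed form", {
  prof <- snr_map(gaussian_stack(1000, 10, 1000, seed = 2))
  expect_equal(mean(prof$snr_db), snr_gaussian_db(1000, 10), tolerance = 0.05)
  # independent Monte-Carlo oracle for the mean absolute deviation
  set.seed(3)
  mad_mc <- mean(abs(rnorm(2e5, 0, 10)))
  expect_equal(20 * log10(1000 / mad_mc), snr_gaussian_db(1000, 10),
               tolerance = 0.1)
  # noise-free stack hits the cap
  const <- array(500, c(8, 4, 5))
  expect_true(all(snr_map(const)$snr_db == 120))
  expect_error(snr_map(array(1, c(4, 4, 1))), "at least 2")
})

test_that("SNR group means follow the center-weighted illumination", {
  cfg <- acquisition_config(n_lines = 1, seed = 13,
                            sensor = sensor_model(read_noise_sigma = 3))
  ctx <- pushbroom:::render_context(scene_white_paper(), cfg)
  P <- pushbroom:::spectral_bin_operator(cfg$cal)
  frames <- lapply(1:40, function(i) {
    fr <- pushbroom:::finish_frame(
      pushbroom:::frame_deterministic(scene_white_paper(), cfg, 0L, ctx),
      cfg, i, 0L)
    pushbroom:::process_frame(fr, cfg, P)
  })
  prof <- snr_map(frames)
  expect_identical(dim(prof$snr_db), c(480L, 100L))
  expect_gt(prof$group_means["center"], prof$group_means["border"])
  expect_named(prof$group_spectra, c("channel", "border", "center", "all"))
})

test_that("spot falloff recovers the half-intensity radius", {
  r150 <- function(n, half) {
    c0 <- (n + 1) / 2
    rr <- sqrt(outer((seq_len(n) - c0)^2, (seq_len(n) - c0)^2, `+`))
    spot_profile(rr, half)
  }
  sf <- spot_falloff(r150(451, 150))
  expect_true(sf$reached)
  expect_equal(sf$half_radius_px, 150, tolerance = 1)
  expect_equal(sf$profile[1], 1)

  flat <- spot_falloff(matrix(1, 101, 101))
  expect_false(flat$reached)
  expect_true(is.na(flat$half_radius_px))

  # similarity: doubling the spatial scale doubles the estimated radius
  sf2 <- spot_falloff(r150(451, 60))
  sf3 <- spot_falloff(r150(451, 120))
  expect_equal(sf3$half_radius_px / sf2$half_radius_px, 2, tolerance = 0.02)

  expect_error(spot_falloff(matrix(1, 10, 10), center = c(50, 50)), "inside")
})

test_that("power-law distance fits are exact on exact data", {
  d <- 5:10
  fit2 <- distance_falloff_fit(d, 300 / d^2)
  expect_equal(fit2$exponent, 2, tolerance = 1e-9)
  expect_equal(fit2$scale, 300, tolerance = 1e-6)
  fit18 <- distance_falloff_fit(d, 120 / d^1.8)
  expect_equal(fit18$exponent, 1.8, tolerance = 1e-9)
  expect_error(distance_falloff_fit(c(5, 5), c(1, 1)), "distinct")
  expect_error(distance_falloff_fit(c(5, -6), c(1, 1)), "positive")
})

test_that("power-law fits stay unbiased under multiplicative noise", {
  d <- 5:10
  p_hat <- vapply(1:300, function(s) {
    set.seed(s)
    i_noisy <- (100 / d^1.8) * exp(rnorm(length(d), 0, 0.02))
    distance_falloff_fit(d, i_noisy)$exponent
  }, numeric(1))
  expect_equal(mean(p_hat), 1.8, tolerance = 0.02)
})

test_that("light sources are equalized at the 650-nm channel", {
  g <- default_grid()
  s1 <- 1 + sin(seq_len(100) / 7)
  f <- equalize_at_wavelength(rbind(s1, s1), g, 650)
  expect_equal(f, c(1, 1))
  f2 <- equalize_at_wavelength(rbind(s1, 2 * s1), g, 650)
  expect_equal(f2[2], 0.5)
  sp <- rbind(light_source("led_nir")$spd[seq(1, 500, by = 5)],
              light_source("xenon")$spd[seq(1, 500, by = 5)],
              light_source("halogen")$spd[seq(1, 500, by = 5)])
  fx <- equalize_at_wavelength(sp, g, 650)
  ch <- which.min(abs(g$centers - 650))
  scaled <- sp * fx
  expect_lt(diff(range(scaled[, ch])) / scaled[1, ch], 1e-12)
  expect_error(equalize_at_wavelength(rbind(c(0, rep(1, 99))), g, 500),
               "positive")
})

test_that("spectral RMSE over a window has its closed forms", {
  g <- default_grid()
  a <- runif(100)
  expect_equal(spectral_rmse(a, a, g, 500, 900), 0)
  expect_equal(spectral_rmse(a, a + 0.03, g, 500, 900), 0.03)
  # even-count window so "offset on half the channels" is exact
  idx <- window_channels(g, 500, 895)
  b <- a
  b[idx[seq_len(length(idx) / 2)]] <- a[idx[seq_len(length(idx) / 2)]] + 0.04
  expect_equal(spectral_rmse(a, b, g, 500, 895), 0.04 / sqrt(2),
               tolerance = 1e-12)
})

test_that("Michelson contrast of a sine profile is exact", {
  t <- seq(0, 2, by = 0.05)          # includes the extremes of cos
  y <- 0.5 + 0.3 * cos(2 * pi * t)
  expect_equal(pushbroom:::sine_contrast(t, y, period = 1), 0.6,
               tolerance = 1e-12)
  # clipping keeps hard two-level profiles at (max-min)/(max+min)
  ysq <- ifelse(abs(t %% 1 - 0.5) < 0.25, 0.05, 0.9)
  expect_equal(pushbroom:::sine_contrast(t, ysq, period = 1),
               (0.9 - 0.05) / (0.9 + 0.05), tolerance = 1e-9)
})

test_that("bar-target resolution matches the Gaussian-MTF prediction", {
  widths <- c(200, 260, 320, 400, 500)
  sigma_mm <- 0.17
  sc <- make_usaf_scene(widths)
  # fundamental-harmonic oracle: square wave 0.05/0.9 blurred by a Gaussian
  mtf <- function(w_mm) exp(-pi^2 * sigma_mm^2 / (2 * w_mm^2))
  pred <- pmin((4 / pi) * 0.425 * mtf(widths / 1000), 0.425) / 0.475
  pred_cutoff <- min(widths[pred >= 0.2])
  expect_identical(pred_cutoff, 320)

  psf <- psf_model(sigma_scan_mm = sigma_mm, sigma_slit_mm = sigma_mm)
  cfg <- quiet_cfg(n_lines = 60, seed = 2, psf = psf,
                   scan_window_mm = c(5.5, 9.5))
  s <- pushbroom::scan(sc, cfg)
  ref <- acquire_references(cfg, n_white_lines = 2)
  cube <- assemble_cube(s$frames, cfg$cal, ref)
  img <- cube$values[, , 1] * ref$white_reflectance   # 500-nm channel
  rep_ac <- michelson_resolution(img, sc, fov_mm = c(4, fov_mm(cfg)[2]),
                                 origin_mm = c(5.5, 0))
  ac <- rep_ac$elements[rep_ac$elements$orientation == "across", ]
  ac <- ac[order(ac$width_um), ]
  # the 200-um element is below the sampling limit at the 0.1-mm pixel
  # pitch and is flagged unmeasurable rather than reported
  expect_false(ac$measurable[1])
  expect_true(all(ac$measurable[-1]))
  # contrasts track the infinite-grating closed form; the finite three-bar
  # triplet and pixel aggregation lower them slightly
  expect_equal(ac$contrast[-1], pred[-1], tolerance = 0.25)
  expect_true(all(ac$contrast[-1] <= pred[-1] + 0.02))
  expect_equal(
    rep_ac$resolved$resolved_width_um[rep_ac$resolved$orientation == "across"],
    pred_cutoff)
  # blur can only reduce contrast relative to the unblurred target
  cfg0 <- quiet_cfg(n_lines = 60, seed = 2, scan_window_mm = c(5.5, 9.5))
  s0 <- pushbroom::scan(sc, cfg0)
  cube0 <- assemble_cube(s0$frames, cfg0$cal,
                         acquire_references(cfg0, n_white_lines = 2))
  rep0 <- michelson_resolution(cube0$values[, , 1] * 0.9, sc,
                               fov_mm = c(4, fov_mm(cfg0)[2]),
                               origin_mm = c(5.5, 0))
  ac0 <- rep0$elements[rep0$elements$orientation == "across", ]
  ac0 <- ac0[order(ac0$width_um), ]
  ok <- ac0$measurable & ac$measurable
  expect_true(all(ac0$contrast[ok] >= ac$contrast[ok] - 1e-6))
})
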