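test_that("scene constructors respect reflectance bounds and patch layout", {
  expect_error(scene_spec("bad", data.frame(x0 = 0, y0 = 0, x1 = 1, y1 = 1,
                                            spec = 1),
                          rbind(rep(1.5, 501)), rep(0.5, 501)),
               "\\[0, 1\\]")
  expect_error(scene_spec("overlap",
                          data.frame(x0 = c(0, 0.5), y0 = c(0, 0.5),
                                     x1 = c(1, 1.5), y1 = c(1, 1.5),
                                     spec = c(1, 1)),
                          rbind(rep(0.5, 501)), rep(0.5, 501)),
               "overlap")
  cc <- scene_colorchecker()
  expect_equal(nrow(cc$patches), 24)
  expect_true(all(cc$spectra >= 0 & cc$spectra <= 1))
  # patch lookup: center of first patch returns its spectrum
  p1 <- cc$patches[1, ]
  r <- scene_reflectance(cc, (p1$x0 + p1$x1) / 2, (p1$y0 + p1$y1) / 2)
  expect_equal(drop(r), cc$spectra[1, ])
})

test_that("bar-target scenes encode triplets at the stated two levels", {
  sc <- make_usaf_scene(c(320))
  expect_equal(nrow(sc$elements), 2)          # both orientations
  expect_setequal(sc$elements$orientation, c("across", "along"))
  # three bars of width 0.32 mm at 0.64-mm pitch per element
  across <- sc$patches[1:3, ]
  expect_equal(across$y1 - across$y0, rep(0.32, 3))
  expect_equal(diff(sort(across$y0)), rep(0.64, 2))
  expect_setequal(round(unique(c(sc$spectra, sc$background)), 2), c(0.05, 0.9))
  # empty list -> blank bright scene
  blank <- make_usaf_scene(numeric(0))
  expect_equal(nrow(blank$patches), 0)
  expect_equal(unique(blank$background), 0.9)
})

test_that("PSF blur mixes patch and background without leaving [min, max]", {
  sc <- make_usaf_scene(c(320))
  psf <- psf_model(sigma_scan_mm = 0.1, sigma_slit_mm = 0.1)
  el <- sc$elements[sc$elements$orientation == "across", ]
  y <- seq(el$cy - 2, el$cy + 2, by = 0.01)
  r <- scene_reflectance(sc, el$cx, y, psf)
  expect_true(all(r >= 0.05 - 1e-9 & r <= 0.9 + 1e-9))
  # far from any patch the blur has no effect
  r_far <- scene_reflectance(sc, el$cx, 45, psf)
  expect_equal(drop(r_far), sc$background, tolerance = 1e-9)
})

test_that("radiance composes reflectance, SPD, spot profile and distance law", {
  flat_light <- light_source("led_nir", spd = rep(1, 501),
                             distance_exponent = 0)
  cfg <- quiet_cfg(n_lines = 4, light = flat_light)
  # unit scene, flat SPD: spectrum constant over wavelength
  r_center <- radiance_at(scene_flat(1), cfg, 1, 479)
  expect_equal(diff(range(r_center)), 0)
  # at the half-intensity radius the value halves (150 px = 7.5 mm here)
  y <- pushbroom:::sample_y_mm(cfg, 960)
  s_half <- which.min(abs(pushbroom:::spot_radius_px(cfg, y) - 150)) - 1L
  r_half <- radiance_at(scene_flat(1), cfg, 1, s_half)
  expect_equal(r_half[1] / r_center[1], 0.5, tolerance = 0.01)
  # doubling the distance with exponent 2 quarters the signal
  l2 <- light_source("led_nir", spd = rep(1, 501), distance_exponent = 2)
  cfg5 <- quiet_cfg(n_lines = 4, light = l2, distance_cm = 5)
  cfg10 <- quiet_cfg(n_lines = 4, light = l2, distance_cm = 10)
  r5 <- radiance_at(scene_flat(1), cfg5, 1, 479)
  # compare at matching spot radius (sample 479 is near center in both)
  r10 <- radiance_at(scene_flat(1), cfg10, 1, 479)
  expect_equal(r10[1] / r5[1], 0.25, tolerance = 1e-6)
})

test_that("raw frame rendering is deterministic and seeded", {
  sc <- scene_white_paper()
  cfg0 <- quiet_cfg(n_lines = 3, seed = 11)
  f1 <- render_raw_frame(sc, cfg0, 1)
  f2 <- render_raw_frame(sc, cfg0, 1)
  expect_identical(f1, f2)
  expect_identical(dim(f1), c(960L, 780L))

  cfgn <- acquisition_config(n_lines = 3, seed = 11)
  g1 <- render_raw_frame(sc, cfgn, 2)
  g2 <- render_raw_frame(sc, cfgn, 2)
  expect_identical(g1, g2)                     # same seed, bit-identical
  cfgn2 <- acquisition_config(n_lines = 3, seed = 12)
  expect_false(identical(g1, render_raw_frame(sc, cfgn2, 2)))
})

test_that("noisy frames average to the noise-free forward model", {
  sc <- scene_white_paper()
  sigma <- 3
  cfg0 <- quiet_cfg(n_lines = 1, seed = 4)
  noise_free <- render_raw_frame(sc, cfg0, 0)
  n <- 400
  acc <- 0
  for (s in 1:n) {
    cfgs <- acquisition_config(n_lines = 1, seed = s,
                               sensor = sensor_model(read_noise_sigma = sigma))
    acc <- acc + render_raw_frame(sc, cfgs, 0)[1:50, 1:50]
  }
  dev <- abs(acc / n - noise_free[1:50, 1:50])
  expect_lt(max(dev), 5 * sigma / sqrt(n))
})

test_that("a scan emits n_lines ordered frames and matching ground truth", {
  cfg <- quiet_cfg(n_lines = 5, seed = 2)
  s <- pushbroom::scan(scene_colorchecker(), cfg)
  expect_length(s$frames, 5)
  expect_equal(vapply(s$frames, attr, 0L, "line_index"), 0:4)
  expect_identical(dim(s$ground_truth$values), c(5L, 480L, 100L))

  s1 <- pushbroom::scan(scene_colorchecker(), quiet_cfg(n_lines = 1))
  expect_length(s1$frames, 1)
  expect_identical(dim(s1$ground_truth$values), c(1L, 480L, 100L))

  cfgn <- acquisition_config(n_lines = 3, seed = 9)
  sa <- pushbroom::scan(scene_white_paper(), cfgn)
  sb <- pushbroom::scan(scene_white_paper(), cfgn)
  expect_identical(sa$frames, sb$frames)       # seeded reproducibility
})

test_that("references capture black level, distance law and validity", {
  cfg <- quiet_cfg(n_lines = 4)
  ref <- acquire_references(cfg, n_white_lines = 2)
  expect_equal(as.vector(ref$dark), rep(64, 480 * 100), tolerance = 1e-12)
  expect_true(all(ref$valid))

  l2 <- light_source("led_nir", distance_exponent = 2)
  ref5 <- acquire_references(quiet_cfg(n_lines = 4, light = l2,
                                       distance_cm = 5), n_white_lines = 2)
  ref10 <- acquire_references(quiet_cfg(n_lines = 4, light = l2,
                                        distance_cm = 10), n_white_lines = 2)
  ratio <- (ref5$white - ref5$dark) / (ref10$white - ref10$dark)
  expect_equal(mean(ratio), 4, tolerance = 1e-6)
})

test_that("a noise-free white scan balances to unit reflectance", {
  cfg <- quiet_cfg(n_lines = 6, seed = 1)
  s <- pushbroom::scan(scene_white_paper(), cfg)
  ref <- acquire_references(cfg, n_white_lines = 4)
  cube <- assemble_cube(s$frames, cfg$cal, ref)
  expect_lt(max(abs(cube$values[cube$mask] - 1)), 1e-6)
})

test_that("sensor QE ripple above 800 nm cancels in white balancing", {
  cfg <- quiet_cfg(n_lines = 4, seed = 1)
  expect_true(cfg$sensor$ripple)
  unit <- scene_flat(1)
  s <- pushbroom::scan(unit, cfg)
  ref <- acquire_references(cfg, white_scene = unit, n_white_lines = 2)
  cube <- assemble_cube(s$frames, cfg$cal, ref)
  expect_lt(max(abs(cube$values[cube$mask] - 1)), 1e-10)
})

test_that("balanced illumination is monotone from the spot center outward", {
  cfg <- quiet_cfg(n_lines = 2)
  ref <- acquire_references(cfg, n_white_lines = 2)
  sig <- ref$white - ref$dark
  for (ch in c(1, 50, 100)) {
    prof <- sig[, ch]
    left <- prof[1:240]; right <- prof[241:480]
    expect_true(all(diff(left) >= -1e-9))      # rises toward the center
    expect_true(all(diff(right) <= 1e-9))      # falls away from it
  }
})

test_that("a noise-free scan recovers per-patch ground-truth spectra", {
  cfg <- quiet_cfg(n_lines = 64, seed = 3)
  sc <- scene_colorchecker()
  s <- pushbroom::scan(sc, cfg)
  ref <- acquire_references(cfg, n_white_lines = 2)
  cube <- assemble_cube(s$frames, cfg$cal, ref)
  # balancing yields reflectance relative to the 0.9 white paper
  rel <- cube$values * ref$white_reflectance
  x <- pushbroom:::line_x_mm(cfg, seq_len(cfg$n_lines) - 1)
  y <- pushbroom:::sample_y_mm(cfg, 480)
  rmse <- vapply(seq_len(nrow(sc$patches)), function(i) {
    p <- sc$patches[i, ]
    li <- which(x > p$x0 + 1 & x < p$x1 - 1)
    si <- which(y > p$y0 + 1 & y < p$y1 - 1)
    if (!length(li) || !length(si)) return(NA_real_)
    got <- apply(rel[li, si, , drop = FALSE], 3, mean)
    want <- apply(s$ground_truth$values[li, si, , drop = FALSE], 3, mean)
    sqrt(mean((got - want)^2))
  }, numeric(1))
  expect_true(sum(!is.na(rmse)) >= 15)         # most patches have interiors
  expect_lt(max(rmse, na.rm = TRUE), 0.005)
})
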