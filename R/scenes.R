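#' Planar test scenes for the pushbroom simulator
#'
#' A scene is a planar target: a background reflectance spectrum plus
#' non-overlapping rectangular patches (mm coordinates, x along the scan
#' direction, y across it, origin at the top-left of the reference
#' field of view), each carrying a reflectance spectrum sampled on the fine
#' 1-nm grid 500--1000 nm.
#'
#' @param name Scene name.
#' @param patches Data frame with columns `x0, y0, x1, y1` (mm) and `spec`
#'   (row index into `spectra`). May have zero rows.
#' @param spectra Matrix `n_spectra x 501` of reflectances in `[0, 1]` on
#'   [fine_wavelengths()].
#' @param background Length-501 reflectance spectrum of the background.
#' @param elements Optional metadata data frame (used by bar-target scenes).
#' @return A `scene_spec`.
#' @export
scene_spec <- function(name, patches, spectra, background, elements = NULL) {
  patches <- as.data.frame(patches)
  spectra <- if (is.null(spectra)) matrix(numeric(), 0, 501) else rbind(spectra)
  if (length(background) != length(fine_wavelengths()))
    stop("`background` must be sampled on the fine 1-nm grid", call. = FALSE)
  if (any(spectra < 0 | spectra > 1) || any(background < 0 | background > 1))
    stop("reflectance spectra must lie in [0, 1]", call. = FALSE)
  if (nrow(patches) > 1L) {
    for (i in seq_len(nrow(patches) - 1L)) for (j in seq(i + 1L, nrow(patches))) {
      if (patches$x0[i] < patches$x1[j] && patches$x1[i] > patches$x0[j] &&
          patches$y0[i] < patches$y1[j] && patches$y1[i] > patches$y0[j])
        stop("scene patches must not overlap", call. = FALSE)
    }
  }
  structure(list(name = name, patches = patches, spectra = spectra,
                 background = background, elements = elements),
            class = "scene_spec")
}

#' @export
print.scene_spec <- function(x, ...) {
  cat(sprintf("<scene_spec> '%s': %d patches\n", x$name, nrow(x$patches)))
  invisible(x)
}

flat_spectrum <- function(level) rep(level, length(fine_wavelengths()))

#' @rdname scene_spec
#' @param reflectance Flat reflectance level.
#' @export
scene_flat <- function(reflectance = 1, name = sprintf("flat_%g", reflectance)) {
  scene_spec(name, data.frame(), NULL, flat_spectrum(reflectance))
}

#' White-paper reference scene (flat reflectance 0.9)
#' @export
scene_white_paper <- function() scene_flat(0.9, "white_paper")

#' Scattering tissue phantom scene
#'
#' Silicone / barium-sulfate style scattering phantom without added
#' absorbers, modeled as an absorber-free flat high reflectance (0.95).
#' @export
scene_phantom <- function() scene_flat(0.95, "phantom")

colorchecker_spectra <- function() {
  lam <- fine_wavelengths()
  sig <- function(l0, s) 1 / (1 + exp(-(lam - l0) / s))
  gauss <- function(l0, s) exp(-0.5 * ((lam - l0) / s)^2)
  sp <- rbind(
    0.06 + 0.55 * sig(590, 18) * (1 - 0.3 * gauss(760, 60)),   # dark skin
    0.20 + 0.55 * sig(570, 25),                                 # light skin
    0.12 + 0.20 * gauss(540, 60) + 0.45 * sig(750, 40),         # blue sky (NIR rise)
    0.08 + 0.30 * gauss(545, 35) + 0.50 * sig(720, 35),         # foliage
    0.18 + 0.25 * gauss(555, 70) + 0.50 * sig(740, 45),         # blue flower
    0.15 + 0.55 * gauss(520, 55) + 0.45 * sig(780, 50),         # bluish green
    0.05 + 0.75 * sig(585, 12),                                 # orange
    0.10 + 0.15 * gauss(530, 40) + 0.55 * sig(760, 45),         # purplish blue
    0.07 + 0.60 * sig(600, 15),                                 # moderate red
    0.06 + 0.15 * gauss(560, 80) + 0.40 * sig(730, 55),         # purple
    0.10 + 0.60 * gauss(555, 45) + 0.45 * sig(770, 50),         # yellow green
    0.06 + 0.78 * sig(570, 20),                                 # orange yellow
    0.05 + 0.12 * gauss(520, 35) + 0.50 * sig(770, 40),         # blue
    0.06 + 0.45 * gauss(540, 30) + 0.45 * sig(750, 40),         # green
    0.05 + 0.70 * sig(610, 12),                                 # red
    0.08 + 0.80 * sig(545, 25),                                 # yellow
    0.09 + 0.55 * sig(590, 30) * (1 - 0.25 * gauss(700, 50)),   # magenta
    0.10 + 0.35 * gauss(510, 30) + 0.40 * sig(760, 45),         # cyan
    matrix(rep(c(0.90, 0.59, 0.36, 0.19, 0.09, 0.03), each = length(lam)),
           nrow = 6, byrow = TRUE)                              # gray ramp
  )
  pmin(pmax(sp, 0), 1)
}

#' ColorChecker-like scene: 24 smooth-spectrum patches in a 6 x 4 grid
#'
#' Patch spectra are smooth synthetic stand-ins (sigmoid/Gaussian mixtures)
#' for the classic 18 chromatic + 6 neutral patches; they are not the
#' published ColorChecker reflectances.
#' @param patch_mm Patch edge length in mm.
#' @param gap_mm Gap between patches in mm.
#' @export
scene_colorchecker <- function(patch_mm = 7, gap_mm = 1.5) {
  sp <- colorchecker_spectra()
  k <- 0L; rows <- list()
  for (r in 0:3) for (c in 0:5) {
    k <- k + 1L
    x0 <- 2 + r * (patch_mm + gap_mm)
    y0 <- 2 + c * (patch_mm + gap_mm)
    rows[[k]] <- data.frame(x0 = x0, y0 = y0, x1 = x0 + patch_mm,
                            y1 = y0 + patch_mm, spec = k)
  }
  scene_spec("colorchecker", do.call(rbind, rows), sp, flat_spectrum(0.25))
}

#' Hemoglobin-bearing tissue scene
#'
#' Patch strip whose absorbance mixes two Gaussian chromophore bands
#' emulating oxy/deoxyhemoglobin absorption (centers 540 and 575 nm) on a
#' flat near-infrared baseline; reflectance is `r0 * 10^(-A)`. The band
#' amplitude parameterizes "hemoglobin content", so sweeping `amplitudes`
#' across patches sweeps the expected hemoglobin index monotonically.
#'
#' @param amplitudes Chromophore band amplitudes, one patch per value.
#' @param nir_absorbance Flat baseline absorbance (optical density).
#' @param r0 Scatter-limited baseline reflectance.
#' @param patch_mm,gap_mm Patch geometry in mm.
#' @export
scene_tissue <- function(amplitudes = seq(0.1, 1.2, length.out = 6),
                         nir_absorbance = 0.15, r0 = 0.7,
                         patch_mm = 7, gap_mm = 1.5) {
  lam <- fine_wavelengths()
  bands <- 0.6 * exp(-0.5 * ((lam - 540) / 10)^2) +
    exp(-0.5 * ((lam - 575) / 14)^2)
  sp <- t(vapply(amplitudes, function(a)
    pmin(pmax(r0 * 10^(-(a * bands + nir_absorbance)), 0), 1),
    numeric(length(lam))))
  n <- length(amplitudes)
  patches <- data.frame(
    x0 = 4, y0 = 2 + (seq_len(n) - 1) * (patch_mm + gap_mm),
    x1 = 4 + 5 * patch_mm, y1 = 2 + (seq_len(n) - 1) * (patch_mm + gap_mm) + patch_mm,
    spec = seq_len(n)
  )
  sc <- scene_spec("tissue", patches, sp, flat_spectrum(0.3))
  sc$amplitudes <- amplitudes
  sc
}

#' Bar-target (USAF-style) resolution scene
#'
#' For each requested line width, a triplet of three dark bars (reflectance
#' 0.05) of that width, separated by equal-width gaps, on a bright ground
#' (0.9), in both orientations: `"across"` (bars stacked along the across-
#' scan y axis, resolution measured across samples) and `"along"` (stacked
#' along the scan x axis). Bar length is five line widths, as on the 1951
#' USAF chart. Element geometry is recorded in `$elements` for
#' [michelson_resolution()].
#'
#' @param line_widths_um Bar line widths in micrometres.
#' @param dark,bright The two reflectance levels.
#' @return A `scene_spec` with an `elements` table (`width_um`,
#'   `orientation`, `cx`, `cy` element centers in mm).
#' @export
make_usaf_scene <- function(line_widths_um, dark = 0.05, bright = 0.9) {
  if (length(line_widths_um) == 0)
    return(scene_spec("usaf", data.frame(), NULL, flat_spectrum(bright),
                      elements = data.frame()))
  if (any(line_widths_um <= 0)) stop("line widths must be positive", call. = FALSE)
  spectra <- rbind(flat_spectrum(dark))
  rows <- list(); elems <- list(); k <- 0L
  y_cursor <- c(across = 3, along = 3)
  x_band <- c(across = 6, along = 26)
  for (w_um in line_widths_um) {
    w <- w_um / 1000
    for (ori in c("across", "along")) {
      cx <- x_band[[ori]] + 2.5 * w
      cy <- y_cursor[[ori]] + 2.5 * w
      for (b in 0:2) {             # three dark bars at offsets -2w, 0, +2w
        off <- (b - 1) * 2 * w
        k <- k + 1L
        rows[[k]] <- if (ori == "across")
          data.frame(x0 = cx - 2.5 * w, y0 = cy + off - w / 2,
                     x1 = cx + 2.5 * w, y1 = cy + off + w / 2, spec = 1)
        else
          data.frame(x0 = cx + off - w / 2, y0 = cy - 2.5 * w,
                     x1 = cx + off + w / 2, y1 = cy + 2.5 * w, spec = 1)
      }
      elems[[length(elems) + 1L]] <-
        data.frame(width_um = w_um, orientation = ori, cx = cx, cy = cy)
      y_cursor[[ori]] <- y_cursor[[ori]] + 5 * w + 2.5
    }
  }
  scene_spec("usaf", do.call(rbind, rows), spectra, flat_spectrum(bright),
             elements = do.call(rbind, elems))
}

#' Scene point-spread-function model
#'
#' Anisotropic Gaussian optical blur applied to the scene before sampling:
#' `sigma_scan_mm` along the scan (x) axis and `sigma_slit_mm` across it
#' (y, the slit axis). `slit_nir_factor` lets the slit sigma grow linearly
#' with wavelength to `slit_nir_factor * sigma_slit_mm` at 1000 nm
#' (reduced across-scan resolution in the near infrared); 1 keeps the blur
#' achromatic.
#' @param sigma_scan_mm,sigma_slit_mm Gaussian sigmas in mm (0 disables).
#' @param slit_nir_factor Relative slit sigma at 1000 nm.
#' @export
psf_model <- function(sigma_scan_mm = 0, sigma_slit_mm = 0, slit_nir_factor = 1) {
  stopifnot(sigma_scan_mm >= 0, sigma_slit_mm >= 0, slit_nir_factor > 0)
  structure(list(sigma_scan_mm = sigma_scan_mm, sigma_slit_mm = sigma_slit_mm,
                 slit_nir_factor = slit_nir_factor), class = "psf_model")
}

slit_sigma_at <- function(psf, lambda_nm) {
  psf$sigma_slit_mm * (1 + (psf$slit_nir_factor - 1) * (lambda_nm - 500) / 500)
}

# one spectrum row per patch (patches may share spectra), background last
patch_spectra <- function(scene) {
  if (nrow(scene$patches))
    rbind(scene$spectra[scene$patches$spec, , drop = FALSE], scene$background)
  else rbind(scene$background)
}

# Patch membership weights at scan position x (scalar, mm) for across-scan
# positions y (vector, mm). Rectangles convolved with the Gaussian PSF have
# separable analytic weights via the normal CDF; sigma = 0 reduces to the
# indicator. Returns length(y) x (n_patches + 1) with the background last.
scene_weights <- function(scene, x, y, sx = 0, sy = 0) {
  np <- nrow(scene$patches)
  W <- matrix(0, length(y), np + 1L)
  if (np > 0) {
    for (i in seq_len(np)) {
      p <- scene$patches[i, ]
      wx <- if (sx > 0) pnorm((p$x1 - x) / sx) - pnorm((p$x0 - x) / sx)
            else as.numeric(x >= p$x0 & x < p$x1)
      if (wx == 0) next
      wy <- if (sy > 0) pnorm((p$y1 - y) / sy) - pnorm((p$y0 - y) / sy)
            else as.numeric(y >= p$y0 & y < p$y1)
      W[, i] <- wx * wy
    }
  }
  W[, np + 1L] <- pmax(1 - rowSums(W[, seq_len(np), drop = FALSE]), 0)
  W
}

#' Scene reflectance at scan position x for a vector of y positions
#'
#' Samples (optionally PSF-blurred) scene reflectance on the fine 1-nm grid.
#' With a chromatic PSF (`slit_nir_factor != 1`) the blur is evaluated at
#' each 5-nm output channel center and interpolated, otherwise a single
#' weight set serves all wavelengths.
#'
#' @param scene A [scene_spec()].
#' @param x Scan position in mm (scalar).
#' @param y Across-scan positions in mm (vector).
#' @param psf Optional [psf_model()].
#' @return Matrix `length(y) x 501` of reflectances.
#' @export
scene_reflectance <- function(scene, x, y, psf = NULL) {
  spectra <- patch_spectra(scene)
  if (is.null(psf) || (psf$sigma_scan_mm == 0 && psf$sigma_slit_mm == 0))
    return(scene_weights(scene, x, y) %*% spectra)
  if (psf$slit_nir_factor == 1 || psf$sigma_slit_mm == 0)
    return(scene_weights(scene, x, y, psf$sigma_scan_mm, psf$sigma_slit_mm) %*% spectra)
  # chromatic slit blur: one weight set per 5-nm channel center
  lam <- fine_wavelengths()
  centers <- seq(502.5, 997.5, by = 5)
  out <- matrix(0, length(y), length(lam))
  for (ci in seq_along(centers)) {
    sy <- slit_sigma_at(psf, centers[ci])
    cols <- which(lam >= centers[ci] - 2.5 & lam < centers[ci] + 2.5)
    if (ci == length(centers)) cols <- c(cols, length(lam))
    W <- scene_weights(scene, x, y, psf$sigma_scan_mm, sy)
    out[, cols] <- (W %*% spectra[, cols, drop = FALSE])
  }
  out
}
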