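#' Per-pixel SNR map from repeated frames
#'
#' For a stack of N nominally identical binned frames, the per-pixel SNR in
#' dB is `20 * log10(mean / mean |I - mean|)`: the denominator is the mean
#' absolute deviation over the stack (for Gaussian noise of sigma this
#' equals `sigma * sqrt(2/pi)`). Pixels with zero deviation are capped at
#' `cap_db`. The map is averaged over the spatial dimension for three line
#' groups -- sensor border (lines 0 to 10), center (240 to 250 on the
#' 480-line geometry, i.e. the 11 central lines) and all lines -- giving
#' SNR-versus-wavelength curves.
#'
#' @param frames List of matrices, or a 3-D array `spatial x channel x N`.
#' @param cap_db Cap for zero-deviation pixels (default 120 dB).
#' @return An `snr_profile`: `snr_db` (spatial x channel), `group_spectra`
#'   (data frame: channel, border, center, all), `group_means` (named
#'   vector), `n_frames`.
#' @export
snr_map <- function(frames, cap_db = 120) {
  if (is.list(frames)) {
    d <- dim(frames[[1]])
    stk <- array(unlist(frames, use.names = FALSE),
                 c(d[1], d[2], length(frames)))
  } else stk <- frames
  d <- dim(stk)
  if (length(d) != 3L || d[3] < 2L)
    stop("need at least 2 frames of identical shape", call. = FALSE)
  m <- rowMeans(stk, dims = 2)
  mad <- rowMeans(abs(stk - as.vector(m)), dims = 2)
  snr <- ifelse(mad > 0 & m > 0, 20 * log10(m / mad), cap_db)
  snr <- pmin(snr, cap_db)
  n <- d[1]
  border <- 1:min(11L, n)
  ctr0 <- floor(n / 2)
  center <- pmax(1L, pmin(n, (ctr0 - 4L):(ctr0 + 6L)))
  groups <- list(border = border, center = unique(center), all = seq_len(n))
  gs <- data.frame(channel = seq_len(d[2]))
  for (g in names(groups))
    gs[[g]] <- colMeans(snr[groups[[g]], , drop = FALSE])
  structure(list(snr_db = snr,
                 group_spectra = gs,
                 group_means = vapply(groups, function(i) mean(snr[i, ]),
                                      numeric(1)),
                 n_frames = d[3], cap_db = cap_db),
            class = "snr_profile")
}

#' @export
print.snr_profile <- function(x, ...) {
  cat(sprintf("<snr_profile> %d x %d from %d frames; mean SNR border %.1f / center %.1f / all %.1f dB\n",
              nrow(x$snr_db), ncol(x$snr_db), x$n_frames,
              x$group_means["border"], x$group_means["center"],
              x$group_means["all"]))
  invisible(x)
}

#' Radial illumination falloff and half-intensity radius
#'
#' Azimuthally averaged relative intensity versus integer pixel radius from
#' the spot center (integer-radius annuli), normalized to 1 at radius 0.
#' The half-intensity radius is found by linear interpolation between the
#' bracketing radii; the instrument shows a ~50% drop at 150 px from the
#' spot center.
#'
#' @param img Intensity image (matrix).
#' @param center `c(row, col)` of the spot center, 1-based (default image
#'   center).
#' @return List with `radius`, `profile` (normalized), `half_radius_px`
#'   (NA if the profile never falls below 0.5 inside the image) and
#'   `reached` flag.
#' @export
spot_falloff <- function(img, center = NULL) {
  d <- dim(img)
  if (is.null(center)) center <- (d + 1) / 2
  if (center[1] < 1 || center[1] > d[1] || center[2] < 1 || center[2] > d[2])
    stop("`center` must lie inside the image", call. = FALSE)
  rr <- sqrt(outer((seq_len(d[1]) - center[1])^2,
                   (seq_len(d[2]) - center[2])^2, `+`))
  ri <- as.integer(round(rr))
  prof <- as.vector(tapply(img, ri, mean))
  radius <- sort(unique(as.vector(ri)))
  prof <- prof / prof[1]
  below <- which(prof < 0.5)
  if (!length(below)) {
    half <- NA_real_; reached <- FALSE
  } else {
    k <- below[1]
    if (k == 1L) half <- radius[1]
    else half <- radius[k - 1] + (0.5 - prof[k - 1]) *
        (radius[k] - radius[k - 1]) / (prof[k] - prof[k - 1])
    reached <- TRUE
  }
  list(radius = radius, profile = prof, half_radius_px = half,
       reached = reached)
}

#' Fit a power-law distance falloff
#'
#' Least-squares line on `(log d, log I)`: intensity modeled as
#' `I = c / d^p`. The instrument shows `p` close to 1.8, near the
#' inverse-square law of a point source.
#'
#' @param distances_cm Positive distances (>= 2 distinct values).
#' @param intensities Positive intensities.
#' @return List with `exponent` (p), `scale` (c) and the `fit` lm object.
#' @export
distance_falloff_fit <- function(distances_cm, intensities) {
  if (length(distances_cm) < 2L || length(unique(distances_cm)) < 2L)
    stop("need at least 2 distinct distances", call. = FALSE)
  if (any(distances_cm <= 0) || any(intensities <= 0))
    stop("distances and intensities must be positive", call. = FALSE)
  fit <- stats::lm(log(intensities) ~ log(distances_cm))
  list(exponent = -unname(coef(fit)[2]),
       scale = exp(unname(coef(fit)[1])),
       fit = fit)
}

#' Equalize spectra at a reference wavelength
#'
#' Scale factors `f_i` such that `f_i * spectrum_i` equals the first
#' spectrum at the channel nearest `lambda0` (`f_1 = 1`); this mirrors the
#' light-source standardization where each source's power is adjusted until
#' the measured intensities at 650 nm agree.
#'
#' @param spectra Matrix (one spectrum per row) or list of spectra on a
#'   common grid.
#' @param grid The spectra's [build_wavelength_grid()].
#' @param lambda0 Reference wavelength in nm (default 650).
#' @return Numeric vector of scale factors.
#' @export
equalize_at_wavelength <- function(spectra, grid, lambda0 = 650) {
  if (is.list(spectra)) spectra <- do.call(rbind, spectra)
  ch <- which.min(abs(grid$centers - lambda0))
  v <- spectra[, ch]
  if (any(v <= 0))
    stop(sprintf("spectrum value at %g nm must be positive", lambda0),
         call. = FALSE)
  unname(v[1] / v)
}

#' Root-mean-square difference between two spectra over a window
#'
#' @param spec_a,spec_b Spectra on the common `grid`.
#' @param grid A [build_wavelength_grid()].
#' @param lo,hi Window in nm (default 500--900, the range used for the
#'   inter-system ColorChecker comparison).
#' @return RMSE (dimensionless for reflectance input).
#' @export
spectral_rmse <- function(spec_a, spec_b, grid, lo = 500, hi = 900) {
  idx <- window_channels(grid, lo, hi)
  sqrt(mean((spec_a[idx] - spec_b[idx])^2))
}

# harmonic regression with fixed period: I(t) = m + A cos + B sin;
# Michelson contrast from the fitted extremes, clipped to the observed range
# so a hard two-level profile yields the plain (max-min)/(max+min) value
sine_contrast <- function(t, y, period) {
  X <- cbind(1, cos(2 * pi * t / period), sin(2 * pi * t / period))
  cf <- tryCatch(qr.solve(X, y), error = function(e) NULL)
  if (is.null(cf)) return(NA_real_)
  m <- cf[1]; a <- sqrt(cf[2]^2 + cf[3]^2)
  imax <- min(m + a, max(y)); imin <- max(m - a, min(y))
  if (!is.finite(imax) || !is.finite(imin) || imax + imin <= 0) return(NA_real_)
  (imax - imin) / (imax + imin)
}

#' Michelson-contrast resolution on a bar target
#'
#' For every bar-triplet element of a [make_usaf_scene()] target imaged in
#' `img`, extracts the across-bar intensity profile (averaged along the
#' central 60% of the bar length), fits a sine of fixed period `2 * width`
#' (only mean, amplitude and phase free -- the period is known from the
#' target geometry, which stabilizes fits near the cutoff), and computes
#' the Michelson contrast `(Imax - Imin) / (Imax + Imin)` from the fitted
#' extremes clipped to the observed profile range. The finest element per
#' orientation with contrast at or above `cutoff` (default 20%) is reported
#' as the resolution.
#'
#' @param img Image matrix (lines x samples), e.g. one spectral channel of
#'   a reflectance cube at a declared wavelength.
#' @param scene The bar-target `scene_spec` (provides element geometry).
#' @param fov_mm `c(x, y)` physical extent of `img` in mm (for a windowed
#'   scan, the window extent).
#' @param cutoff Michelson contrast cutoff (default 0.20).
#' @param origin_mm `c(x, y)` scene coordinates of the image's top-left
#'   corner.
#' @return A `resolution_report`: `elements` data frame (width_um,
#'   orientation, contrast, measurable), `resolved` data frame of the
#'   finest resolved width per orientation, `cutoff`.
#' @export
michelson_resolution <- function(img, scene, fov_mm, cutoff = 0.20,
                                 origin_mm = c(0, 0)) {
  if (is.null(scene$elements) || !nrow(scene$elements))
    stop("scene has no bar-target elements", call. = FALSE)
  d <- dim(img)
  pitch_x <- fov_mm[1] / d[1]   # mm per line
  pitch_y <- fov_mm[2] / d[2]   # mm per sample
  x_mm <- origin_mm[1] + (seq_len(d[1]) - 0.5) * pitch_x
  y_mm <- origin_mm[2] + (seq_len(d[2]) - 0.5) * pitch_y
  el <- scene$elements
  el$contrast <- NA_real_
  el$measurable <- FALSE
  for (i in seq_len(nrow(el))) {
    w <- el$width_um[i] / 1000
    cx <- el$cx[i]; cy <- el$cy[i]
    if (el$orientation[i] == "across") {
      prof_sel <- abs(y_mm - cy) <= w
      avg_sel <- abs(x_mm - cx) <= 1.5 * w
      if (sum(prof_sel) < 5L || sum(avg_sel) < 1L) next
      p <- colMeans(img[avg_sel, prof_sel, drop = FALSE])
      t <- y_mm[prof_sel] - cy
    } else {
      prof_sel <- abs(x_mm - cx) <= w
      avg_sel <- abs(y_mm - cy) <= 1.5 * w
      if (sum(prof_sel) < 5L || sum(avg_sel) < 1L) next
      p <- rowMeans(img[prof_sel, avg_sel, drop = FALSE])
      t <- x_mm[prof_sel] - cx
    }
    cst <- sine_contrast(t, p, period = 2 * w)
    if (is.finite(cst)) {
      el$contrast[i] <- cst
      el$measurable[i] <- TRUE
    }
  }
  resolved <- do.call(rbind, lapply(split(el, el$orientation), function(e) {
    ok <- e$measurable & e$contrast >= cutoff
    data.frame(orientation = e$orientation[1],
               resolved_width_um = if (any(ok)) min(e$width_um[ok]) else NA_real_)
  }))
  rownames(resolved) <- NULL
  structure(list(elements = el, resolved = resolved, cutoff = cutoff),
            class = "resolution_report")
}

#' @export
print.resolution_report <- function(x, ...) {
  cat(sprintf("<resolution_report> cutoff %.0f%%\n", 100 * x$cutoff))
  print(x$resolved)
  invisible(x)
}
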