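#' Fit the spectrograph wavelength calibration
#'
#' Least-squares polynomial mapping spectral-pixel index (0-based, 0..779 for
#' the default readout) to wavelength in nm, anchored on emission lines of a
#' calibration lamp (a krypton lamp on the real instrument). The fitted map
#' must be strictly increasing over the full pixel range; a non-monotone fit
#' is a calibration failure.
#'
#' @param anchors Data frame (or 2-column matrix) with columns `pixel`
#'   (spectral-pixel position, may be fractional) and `wavelength` (nm).
#' @param degree Polynomial degree; default 2, the usual model for a grating
#'   spectrograph over a 500-nm span.
#' @param n_pixels Number of spectral pixels the calibration must cover
#'   (monotonicity is checked over `0 .. n_pixels - 1`).
#' @return A `spectral_cal`: list with `coeffs` (ascending powers, nm),
#'   `anchors` (with per-anchor `residual` in nm), `degree`, `n_pixels`.
#' @examples
#' a <- data.frame(pixel = c(89, 136, 406, 420, 445, 497, 588),
#'                 wavelength = c(557.03, 587.09, 760.15, 769.45,
#'                                785.48, 819.01, 877.67))
#' cal <- fit_spectral_calibration(a, degree = 2)
#' max(abs(cal$anchors$residual))
#' @export
fit_spectral_calibration <- function(anchors, degree = 2L, n_pixels = 780L) {
  anchors <- as.data.frame(anchors)
  if (ncol(anchors) < 2L) stop("`anchors` needs columns pixel, wavelength", call. = FALSE)
  names(anchors)[1:2] <- c("pixel", "wavelength")
  if (anyDuplicated(anchors$pixel))
    stop("anchor pixel positions must be distinct", call. = FALSE)
  if (nrow(anchors) < degree + 1L)
    stop(sprintf("need at least %d anchors for degree %d", degree + 1L, degree),
         call. = FALSE)
  # raw-polynomial least squares; degrees here are tiny so conditioning is fine
  X <- outer(anchors$pixel, 0:degree, `^`)
  coeffs <- as.vector(qr.solve(X, anchors$wavelength))
  fitted <- as.vector(X %*% coeffs)
  anchors$residual <- anchors$wavelength - fitted
  cal <- structure(
    list(coeffs = coeffs, anchors = anchors, degree = degree,
         n_pixels = as.integer(n_pixels)),
    class = "spectral_cal"
  )
  w <- cal_wavelengths(cal)
  if (any(diff(w) <= 0))
    stop("calibration failure: fitted pixel-to-wavelength map is not strictly increasing",
         call. = FALSE)
  cal
}

#' Evaluate a spectral calibration
#'
#' @param cal A `spectral_cal`.
#' @param pixels Spectral-pixel positions (0-based); defaults to the full
#'   readout `0 .. n_pixels - 1`.
#' @return Wavelengths in nm.
#' @export
cal_wavelengths <- function(cal, pixels = seq_len(cal$n_pixels) - 1) {
  drop(outer(pixels, seq_along(cal$coeffs) - 1, `^`) %*% cal$coeffs)
}

#' @export
print.spectral_cal <- function(x, ...) {
  cat(sprintf("<spectral_cal> degree %d over %d spectral pixels\n",
              x$degree, x$n_pixels))
  cat("  coeffs:", format(x$coeffs, digits = 8), "\n")
  if (nrow(x$anchors))
    cat(sprintf("  %d anchors, max |residual| %.3g nm\n",
                nrow(x$anchors), max(abs(x$anchors$residual))))
  invisible(x)
}

#' Krypton-lamp emission-line anchor set
#'
#' Seven Kr I emission lines (nm, standard atomic line tables) in the
#' 500--1000 nm band, paired with the spectral-pixel positions they fall on
#' under a given true pixel-to-wavelength map. Used by the simulator to set
#' up its default calibration.
#'
#' @param true_coeffs Ascending-power polynomial of the true map; the default
#'   is the simulator's sensor model.
#' @return Data frame with columns `pixel`, `wavelength`.
#' @export
krypton_anchors <- function(true_coeffs = c(500, 0.63, 1e-5)) {
  lines_nm <- c(557.029, 587.092, 760.155, 769.454, 785.482, 819.006, 877.675)
  # invert the (monotone) polynomial per line
  px <- vapply(lines_nm, function(w) {
    uniroot(function(p) drop(outer(p, seq_along(true_coeffs) - 1, `^`) %*% true_coeffs) - w,
            interval = c(-50, 2000), tol = 1e-12)$root
  }, numeric(1))
  data.frame(pixel = px, wavelength = lines_nm)
}

#' Simulator default spectrograph calibration
#'
#' Degree-2 calibration fitted to the [krypton_anchors()] of the simulator's
#' true pixel-to-wavelength map `500 + 0.63 p + 1e-5 p^2` (spanning roughly
#' 500--997 nm over the 780 spectral pixels).
#' @return A `spectral_cal`.
#' @export
default_calibration <- function() {
  fit_spectral_calibration(krypton_anchors(), degree = 2L, n_pixels = 780L)
}

#' Write / read a spectral calibration as structured text
#'
#' Small key-value text format: degree, number of pixels, coefficients
#' (ascending powers), and the anchor table.
#'
#' @param cal A `spectral_cal`.
#' @param path File path.
#' @return `write_calibration` returns `path` invisibly; `read_calibration`
#'   returns the `spectral_cal`.
#' @export
write_calibration <- function(cal, path) {
  lines <- c(
    "pushbroom spectral calibration",
    sprintf("degree = %d", cal$degree),
    sprintf("n_pixels = %d", cal$n_pixels),
    paste("coeffs =", paste(format(cal$coeffs, digits = 17), collapse = " ")),
    "anchors: pixel wavelength",
    sprintf("%.10f %.6f", cal$anchors$pixel, cal$anchors$wavelength)
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  lines <- readLines(path)
  get_val <- function(key) {
    ln <- grep(paste0("^", key, " ="), lines, value = TRUE)
    if (!length(ln)) stop(sprintf("calibration file missing `%s`", key), call. = FALSE)
    sub(paste0("^", key, " = *"), "", ln[1])
  }
  degree <- as.integer(get_val("degree"))
  n_pixels <- as.integer(get_val("n_pixels"))
  i <- grep("^anchors:", lines)
  anc <- do.call(rbind, lapply(lines[seq(i + 1L, length(lines))], function(l)
    as.numeric(strsplit(trimws(l), " +")[[1]])))
  fit_spectral_calibration(
    data.frame(pixel = anc[, 1], wavelength = anc[, 2]),
    degree = degree, n_pixels = n_pixels
  )
}

#' Assign spectral pixels to calibrated wavelength channels
#'
#' Maps each spectral pixel of a raw line frame to the channel of `grid`
#' whose center is nearest its calibrated wavelength. Pixels sharing a
#' channel are averaged; channels receiving no pixel are filled by linear
#' interpolation from the nearest populated neighbors (end channels by
#' nearest-neighbor). Wavelengths falling outside the grid by more than one
#' channel spacing trigger a warning and are clipped to the end channels.
#'
#' On the default readout this turns a 960 x 780 (spatial x spectral-pixel)
#' frame into a 960 x 500 frame on the 1-nm calibration grid.
#'
#' @param frame Numeric matrix, spatial x spectral-pixel.
#' @param cal A `spectral_cal` covering `ncol(frame)` pixels.
#' @param grid Target [build_wavelength_grid()]; default [calibration_grid()].
#' @return Numeric matrix spatial x `length(grid)` with attribute
#'   `"grid"` set to `grid`.
#' @export
map_spectral_axis <- function(frame, cal, grid = calibration_grid()) {
  frame <- as.matrix(frame)
  np <- ncol(frame)
  lam <- cal_wavelengths(cal, seq_len(np) - 1)
  n <- length(grid$centers)
  k <- round((lam - grid$centers[1]) / grid$spacing)
  if (any(k < -1) || any(k > n))
    warning("calibrated wavelengths extend beyond the grid by more than one spacing; clipped to end channels")
  ch <- pmin(pmax(k, 0), n - 1) + 1L
  cnt <- tabulate(ch, nbins = n)
  sums <- rowsum(t(frame), group = ch)        # populated-channel sums x spatial
  filled <- sort(unique(ch))
  out <- matrix(NA_real_, nrow(frame), n)
  out[, filled] <- t(sums / cnt[filled])
  empty <- which(cnt == 0L)
  if (length(empty)) {
    # linear interpolation between bracketing populated channels,
    # constant continuation at the ends
    lo <- filled[pmax(findInterval(empty, filled), 1L)]
    hi_idx <- pmin(findInterval(empty, filled) + 1L, length(filled))
    hi <- filled[hi_idx]
    w <- ifelse(hi == lo, 0, (empty - lo) / (hi - lo))
    out[, empty] <- out[, lo, drop = FALSE] * rep(1 - w, each = nrow(out)) +
      out[, hi, drop = FALSE] * rep(w, each = nrow(out))
  }
  attr(out, "grid") <- grid
  out
}

# Fused linear operator for wavelength assignment + spectral binning:
# a n_pixels x (length(grid)/spectral_factor) matrix P such that
# frame %*% P == bin_frame(map_spectral_axis(frame, cal, grid))'s spectral
# stage. Both stages are linear in the pixel values (per-channel averaging,
# interpolation of empty channels, block means), so composing their weights
# once per calibration makes streaming assembly a single matrix product.
spectral_bin_operator <- function(cal, grid = calibration_grid(),
                                  spectral_factor = 5L) {
  n <- length(grid$centers)
  lam <- cal_wavelengths(cal)
  ch <- pmin(pmax(round((lam - grid$centers[1]) / grid$spacing), 0), n - 1) + 1L
  cnt <- tabulate(ch, nbins = n)
  A <- matrix(0, n, cal$n_pixels)
  A[cbind(ch, seq_len(cal$n_pixels))] <- 1 / cnt[ch]
  empty <- which(cnt == 0L)
  if (length(empty)) {
    filled <- which(cnt > 0L)
    lo <- filled[pmax(findInterval(empty, filled), 1L)]
    hi <- filled[pmin(findInterval(empty, filled) + 1L, length(filled))]
    w <- ifelse(hi == lo, 0, (empty - lo) / (hi - lo))
    A[empty, ] <- (1 - w) * A[lo, , drop = FALSE] + w * A[hi, , drop = FALSE]
  }
  B <- matrix(0, n, n %/% spectral_factor)
  B[cbind(seq_len(n), rep(seq_len(n %/% spectral_factor), each = spectral_factor))] <-
    1 / spectral_factor
  t(A) %*% B
}

#' Bin a calibrated frame spatially and spectrally
#'
#' Non-overlapping block means: the device averages 2 pixels in the spatial
#' dimension and 5 channels in the spectral dimension, reducing a 960 x 500
#' calibrated frame to 480 x 100 for noise reduction. The grand mean is
#' preserved exactly for divisible shapes.
#'
#' @param frame Numeric matrix, spatial x channel (e.g. from
#'   [map_spectral_axis()]).
#' @param spatial_factor,spectral_factor Integer block sizes; both must
#'   divide the corresponding dimension.
#' @return Numeric matrix (spatial/spatial_factor) x (channel/spectral_factor)
#'   with a `"grid"` attribute rebuilt over the same wavelength range.
#' @export
bin_frame <- function(frame, spatial_factor = 2L, spectral_factor = 5L) {
  g <- attr(frame, "grid")
  frame <- as.matrix(frame)
  nr <- nrow(frame); nc <- ncol(frame)
  if (nr %% spatial_factor != 0L || nc %% spectral_factor != 0L)
    stop("frame dimensions must be divisible by the binning factors", call. = FALSE)
  x <- rowsum(frame, group = rep(seq_len(nr %/% spatial_factor), each = spatial_factor))
  x <- t(rowsum(t(x), group = rep(seq_len(nc %/% spectral_factor), each = spectral_factor)))
  x <- x / (spatial_factor * spectral_factor)
  dimnames(x) <- NULL
  if (!is.null(g))
    attr(x, "grid") <- build_wavelength_grid(nc %/% spectral_factor, g$range_lo, g$range_hi)
  x
}
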