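#' Dark / white reference set for reflectance balancing
#'
#' Bundles the mean dark pattern (sensor response with illumination off,
#' including the black level) and the per-distance white reference (mean
#' response on white paper at the acquisition distance), both on the binned
#' 480 x 100 geometry. A validity mask marks pixels where the white signal
#' does not exceed the dark pattern.
#'
#' @param dark,white Numeric matrices of identical shape (spatial x channel),
#'   in counts.
#' @param distance_cm Acquisition distance the white reference was measured
#'   at, in cm.
#' @param white_reflectance Reflectance of the physical white reference
#'   (default 0.9 for white paper). Metadata only: balancing follows the
#'   plain dark/white normalisation, so reflectance values are relative to
#'   this reference.
#' @param eps Denominator guard in counts: pixels with
#'   `white - dark <= eps` are marked invalid.
#' @return A `reference_set`: list with `dark`, `white`, `distance_cm`,
#'   `white_reflectance`, `valid` (logical matrix), `eps`.
#' @export
reference_set <- function(dark, white, distance_cm = NA_real_,
                          white_reflectance = 0.9, eps = 1e-6) {
  dark <- as.matrix(dark); white <- as.matrix(white)
  if (!all(dim(dark) == dim(white)))
    stop("`dark` and `white` must have identical shape", call. = FALSE)
  valid <- (white - dark) > eps
  if (!any(valid))
    stop("balancing failure: white reference nowhere exceeds the dark pattern",
         call. = FALSE)
  structure(
    list(dark = dark, white = white, distance_cm = distance_cm,
         white_reflectance = white_reflectance, valid = valid, eps = eps),
    class = "reference_set"
  )
}

#' @export
print.reference_set <- function(x, ...) {
  cat(sprintf("<reference_set> %d x %d, distance %s cm, %.1f%% valid pixels\n",
              nrow(x$dark), ncol(x$dark), format(x$distance_cm),
              100 * mean(x$valid)))
  invisible(x)
}

new_hyper_cube <- function(values, grid, mask, meta = list(), kind = "reflectance") {
  structure(
    list(values = values, grid = grid, mask = mask, meta = meta),
    class = c(paste0(kind, "_cube"), "hyper_cube")
  )
}

#' @export
print.hyper_cube <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<%s> %d lines x %d samples x %d channels (%g-%g nm), %.1f%% valid\n",
              class(x)[1], d[1], d[2], d[3],
              x$grid$centers[1], x$grid$centers[length(x$grid$centers)],
              100 * mean(x$mask)))
  invisible(x)
}

#' Dark/white reflectance balancing
#'
#' Converts measured intensities to reflectance relative to the white
#' reference: `I_R = (I0 - I_dark) / (I_white - I_dark)`, element-wise per
#' spatial pixel and channel. The dark and white references (one frame each)
#' are broadcast across scan lines. Pixels where the denominator does not
#' exceed `ref$eps` are masked invalid; values are clipped to `[0, cap]`
#' (glare pixels can exceed 1).
#'
#' Illumination geometry, light-source spectrum and sensor quantum
#' efficiency -- including the QE ripple above 800 nm -- cancel in this
#' ratio, which is why white balancing removes them.
#'
#' @param i0 Acquired intensity: lines x samples x channels array, or a
#'   single samples x channels matrix (treated as a one-line cube).
#' @param ref A [reference_set()] matching the samples x channels geometry.
#' @param grid [build_wavelength_grid()] of the spectral axis; default
#'   [default_grid()].
#' @param cap Upper clip for reflectance (default 4).
#' @param meta Optional named list stored on the cube (distance, light
#'   source, seed, ...).
#' @return A `reflectance_cube`: `values` (lines x samples x channels in
#'   `[0, cap]`), `grid`, `mask` (same shape, `TRUE` = valid), `meta`.
#' @export
compute_reflectance <- function(i0, ref, grid = default_grid(), cap = 4,
                                meta = list()) {
  if (is.matrix(i0)) i0 <- array(i0, c(1L, dim(i0)))
  d <- dim(i0)
  if (length(d) != 3L || d[2] != nrow(ref$dark) || d[3] != ncol(ref$dark))
    stop("`i0` must be lines x samples x channels matching the reference geometry",
         call. = FALSE)
  n_lines <- d[1]
  # broadcast the per-frame references across scan lines
  dark3 <- aperm(array(ref$dark, c(d[2], d[3], n_lines)), c(3, 1, 2))
  den3 <- aperm(array(ref$white - ref$dark, c(d[2], d[3], n_lines)), c(3, 1, 2))
  vals <- (i0 - dark3) / den3
  mask <- den3 > ref$eps
  if (!any(mask))
    stop("balancing failure: denominator nowhere exceeds eps", call. = FALSE)
  vals[!mask] <- 0
  vals <- pmin(pmax(vals, 0), cap)
  meta$distance_cm <- meta$distance_cm %||% ref$distance_cm
  new_hyper_cube(vals, grid, mask, meta, kind = "reflectance")
}

#' Absorbance from reflectance
#'
#' `A = -log10(max(I_R, floor))`; the floor bounds the optical density for
#' zero-reflectance pixels. The validity mask is propagated unchanged.
#'
#' @param refl A `reflectance_cube` from [compute_reflectance()].
#' @param floor Reflectance floor before the log (default 1e-4, i.e. maximum
#'   absorbance 4 optical densities).
#' @return An `absorbance_cube` with the same geometry.
#' @export
compute_absorbance <- function(refl, floor = 1e-4) {
  stopifnot(inherits(refl, "hyper_cube"))
  vals <- -log10(pmax(refl$values, floor))
  new_hyper_cube(vals, refl$grid, refl$mask, refl$meta, kind = "absorbance")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
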