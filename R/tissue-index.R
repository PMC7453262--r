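#' Channels inside a wavelength window
#'
#' Indices of the channels whose centers satisfy `lo <= center <= hi`
#' (inclusive at both ends). On the default 5-nm grid the hemoglobin
#' windows select 13 channels (530--590 nm) and 9 channels (785--825 nm).
#'
#' @param grid A [build_wavelength_grid()] grid.
#' @param lo,hi Window bounds in nm.
#' @return Integer channel indices (1-based).
#' @export
window_channels <- function(grid, lo, hi) {
  if (lo > hi) stop("`lo` must not exceed `hi`", call. = FALSE)
  idx <- which(grid$centers >= lo & grid$centers <= hi)
  if (!length(idx))
    stop(sprintf("no channel centers inside [%g, %g] nm", lo, hi), call. = FALSE)
  idx
}

#' Per-pixel mean absorbance over a wavelength window
#'
#' @param cube An `absorbance_cube`.
#' @param lo,hi Window bounds in nm.
#' @return List with `values` (lines x samples matrix) and `valid`
#'   (a pixel is valid only if valid in every channel of the window).
#' @export
mean_window_absorbance <- function(cube, lo, hi) {
  idx <- window_channels(cube$grid, lo, hi)
  sub <- cube$values[, , idx, drop = FALSE]
  vals <- apply(sub, c(1, 2), mean)
  valid <- apply(cube$mask[, , idx, drop = FALSE], c(1, 2), all)
  list(values = vals, valid = valid)
}

#' Organ hemoglobin index (OHI)
#'
#' Ratio of the mean absorbance in the hemoglobin absorption band
#' (530--590 nm) to the near-infrared band (785--825 nm), affinely rescaled
#' to a 0--100 display range:
#' `OHI = clip(100 * 0.5 * (r - a) / (b - a), 0, 100)` with
#' `r = meanA(530..590) / meanA(785..825)`. The calibration constants `a`
#' and `b` tie the scale to a reference instrument; the defaults
#' (`a = 0, b = 2`) are uncalibrated placeholders, so absolute agreement
#' with any commercial device's index is not claimed. Pixels whose NIR-band
#' mean absorbance is below `eps` are masked rather than divided.
#'
#' @param cube An `absorbance_cube` on a grid covering both windows.
#' @param a,b Calibration constants, `b > a`.
#' @param vis_window,nir_window Window bounds in nm.
#' @param eps Minimum NIR mean absorbance.
#' @return An `index_image`: `values` (lines x samples, in `[0, 100]`),
#'   `valid`, `name`, `calibration`, `ratio` (the unscaled `r`).
#' @export
ohi <- function(cube, a = 0, b = 2, vis_window = c(530, 590),
                nir_window = c(785, 825), eps = 1e-6) {
  if (b <= a) stop("`b` must exceed `a`", call. = FALSE)
  vis <- mean_window_absorbance(cube, vis_window[1], vis_window[2])
  nir <- mean_window_absorbance(cube, nir_window[1], nir_window[2])
  valid <- vis$valid & nir$valid & nir$values > eps
  r <- vis$values / nir$values
  r[!valid] <- NA_real_
  vals <- pmin(pmax(100 * 0.5 * (r - a) / (b - a), 0), 100)
  structure(
    list(values = vals, valid = valid, name = "OHI",
         calibration = c(a = a, b = b), ratio = r),
    class = "index_image"
  )
}

#' @export
print.index_image <- function(x, ...) {
  cat(sprintf("<index_image> %s, %d x %d, a = %g, b = %g, %.1f%% valid\n",
              x$name, nrow(x$values), ncol(x$values),
              x$calibration["a"], x$calibration["b"], 100 * mean(x$valid)))
  invisible(x)
}

#' False-color rendering of an index image
#'
#' Deterministic pointwise mapping of the 0--100 index onto a color ramp
#' (any palette name accepted by [grDevices::hcl.colors()], 256 steps);
#' masked pixels are rendered neutral gray.
#'
#' @param img An `index_image`.
#' @param colormap Palette name (default `"Viridis"`).
#' @param gray Gray level for masked pixels.
#' @return List with `rgb` (rows x cols x 3 array in `[0, 1]`) and
#'   `scale_bar` (data frame of index values and hex colors).
#' @export
render_index <- function(img, colormap = "Viridis", gray = 0.5) {
  pal <- grDevices::hcl.colors(256, colormap)
  ramp <- grDevices::col2rgb(pal) / 255
  v <- img$values
  d <- dim(v)
  bin <- pmin(pmax(floor(v / 100 * 255) + 1L, 1L), 256L)
  out <- array(gray, c(d[1], d[2], 3))
  ok <- img$valid & is.finite(v)
  for (k in 1:3) {
    plane <- matrix(gray, d[1], d[2])
    plane[ok] <- ramp[k, bin[ok]]
    out[, , k] <- plane
  }
  list(rgb = out,
       scale_bar = data.frame(value = seq(0, 100, length.out = 256),
                              color = pal))
}

#' Write an index image as a single-band float raster
#'
#' Same ENVI-style dialect as [write_cube()], with one band and the index
#' name recorded in the header.
#' @param img An `index_image`.
#' @param path Output path.
#' @export
write_index_raster <- function(img, path) {
  cube <- new_hyper_cube(array(img$values, c(dim(img$values), 1L)),
                         build_wavelength_grid(1L, 0, 1),
                         array(img$valid, c(dim(img$values), 1L)),
                         list(index = img$name,
                              a = img$calibration[["a"]],
                              b = img$calibration[["b"]]),
                         kind = "index")
  write_cube(cube, path)
}
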