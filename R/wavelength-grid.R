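#' Build a uniform wavelength grid
#'
#' Constructs the spectral axis of a hyperspectral cube: `n_channels` channel
#' centers at `lo + k * spacing`, `k = 0 .. n_channels - 1`, with
#' `spacing = (hi - lo) / n_channels`. The device default is 100 channels over
#' 500--1000 nm (5-nm spacing, centers 500, 505, ..., 995 nm); the pre-binning
#' calibration axis uses 500 channels over the same range (1-nm spacing).
#'
#' @param n_channels Number of channels (>= 1).
#' @param lo,hi Wavelength range in nm; `hi > lo`.
#' @return A `wavelength_grid`: list with `centers` (nm), `spacing` (nm),
#'   `range_lo`, `range_hi`.
#' @examples
#' g <- build_wavelength_grid(100, 500, 1000)
#' head(g$centers)
#' @export
build_wavelength_grid <- function(n_channels, lo, hi) {
  if (length(n_channels) != 1L || n_channels < 1 || n_channels != round(n_channels))
    stop("`n_channels` must be a positive integer", call. = FALSE)
  if (!is.finite(lo) || !is.finite(hi) || hi <= lo)
    stop("wavelength span must be positive (`hi` > `lo`)", call. = FALSE)
  spacing <- (hi - lo) / n_channels
  structure(
    list(
      centers = lo + (seq_len(n_channels) - 1) * spacing,
      spacing = spacing,
      range_lo = lo,
      range_hi = hi
    ),
    class = "wavelength_grid"
  )
}

#' @export
print.wavelength_grid <- function(x, ...) {
  cat(sprintf(
    "<wavelength_grid> %d channels, %g-%g nm, spacing %g nm\n",
    length(x$centers), x$range_lo, x$range_hi, x$spacing
  ))
  invisible(x)
}

#' @export
length.wavelength_grid <- function(x) length(x$centers)

#' Default output grid (100 channels, 500-1000 nm, 5 nm)
#' @return A [build_wavelength_grid()] grid.
#' @export
default_grid <- function() build_wavelength_grid(100L, 500, 1000)

#' Pre-binning calibration grid (500 channels, 500-1000 nm, 1 nm)
#' @return A [build_wavelength_grid()] grid.
#' @export
calibration_grid <- function() build_wavelength_grid(500L, 500, 1000)

# fine internal grid used by the scene / light-source forward models: 1-nm
# sampling including both endpoints (501 samples)
fine_wavelengths <- function() seq(500, 1000, by = 1)
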