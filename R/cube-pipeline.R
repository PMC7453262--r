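#' Assemble a reflectance cube from a stream of raw line frames
#'
#' Streaming counterpart of the on-device processing: each incoming raw
#' frame is wavelength-calibrated ([map_spectral_axis()]), binned
#' ([bin_frame()]) and dark/white balanced, and written into the cube as it
#' arrives. An optional callback is invoked once per line with the partial
#' cube, mirroring the live false-color preview available during scanning;
#' because each line is processed independently, the streamed result is
#' bit-identical to batch processing.
#'
#' @param frames Either a list of raw frames (matrices, spatial x
#'   spectral-pixel) in line order -- `line_index` attributes, when present,
#'   must be consecutive starting at 0 -- or a generator
#'   `function(line)` returning the raw frame for 0-based `line` (then
#'   `n_lines` or `cfg` must give the line count). The generator form keeps
#'   only one raw frame in memory at a time, which is how full-scale scans
#'   (640 x 960 x 780 samples) are assembled.
#' @param n_lines Number of lines when `frames` is a generator.
#' @param cal A `spectral_cal`.
#' @param ref A [reference_set()] on the binned geometry.
#' @param on_line Optional `function(partial_values, line)` called after
#'   each line (1-based `line`); lines not yet received are `NA`.
#' @param cfg Optional [acquisition_config()] whose geometry is recorded in
#'   the cube metadata.
#' @param grid Output spectral axis (default [default_grid()]).
#' @param cap Reflectance clip, as in [compute_reflectance()].
#' @return A `reflectance_cube` with `n_lines x 480 x 100` values for the
#'   default readout.
#' @export
assemble_cube <- function(frames, cal, ref, on_line = NULL, cfg = NULL,
                          grid = default_grid(), cap = 4, n_lines = NULL) {
  if (is.function(frames)) {
    n <- n_lines %||% cfg$n_lines
    if (is.null(n)) stop("generator input needs `n_lines` (or `cfg`)", call. = FALSE)
    get_frame <- function(l) {
      f <- frames(l - 1L)
      li <- attr(f, "line_index")
      if (!is.null(li) && li != l - 1L)
        stop("stream integrity error: frames out of order or missing lines",
             call. = FALSE)
      f
    }
  } else {
    n <- length(frames)
    if (n < 1L) stop("empty frame stream", call. = FALSE)
    idx <- vapply(frames, function(f) {
      li <- attr(f, "line_index")
      if (is.null(li)) NA_real_ else as.numeric(li)
    }, numeric(1))
    if (!all(is.na(idx)) && !identical(idx, as.numeric(seq_len(n) - 1)))
      stop("stream integrity error: frames out of order or missing lines",
           call. = FALSE)
    get_frame <- function(l) frames[[l]]
  }
  ns <- nrow(ref$dark); nc <- ncol(ref$dark)
  vals <- array(NA_real_, c(n, ns, nc))
  mask <- array(FALSE, c(n, ns, nc))
  grid1 <- calibration_grid()
  P <- spectral_bin_operator(cal, grid1, length(grid1) %/% nc)
  den <- ref$white - ref$dark
  ok <- den > ref$eps
  for (l in seq_len(n)) {
    fr <- get_frame(l)
    sf <- nrow(fr) %/% ns
    x <- unclass(fr) %*% P
    b <- rowsum(x, group = rep(seq_len(ns), each = sf)) / sf
    r <- (b - ref$dark) / den
    r[!ok] <- 0
    vals[l, , ] <- pmin(pmax(r, 0), cap)
    mask[l, , ] <- ok
    if (!is.null(on_line)) on_line(vals, l)
  }
  meta <- list(distance_cm = ref$distance_cm)
  if (!is.null(cfg)) {
    meta$distance_cm <- cfg$distance_cm
    meta$light <- cfg$light$name
    meta$seed <- cfg$seed
    meta$fov_mm <- fov_mm(cfg)
    meta$scan_window_mm <- scan_window(cfg)
  }
  new_hyper_cube(vals, grid, mask, meta, kind = "reflectance")
}

#' Acquisition time of a scan
#'
#' `n_lines / frame_rate`, reported at 0.1-s resolution: the device records
#' 640 line frames at 140 fps, i.e. 4.6 s.
#'
#' @param cfg An [acquisition_config()] (its sensor holds the frame rate).
#' @return Seconds, rounded to one decimal.
#' @export
acquisition_time <- function(cfg) {
  fr <- cfg$sensor$frame_rate
  if (fr <= 0) stop("frame rate must be positive", call. = FALSE)
  round(cfg$n_lines / fr, 1)
}

#' Pseudocolor rendering of a reflectance cube
#'
#' Three display channels formed by averaging reflectance over three fixed
#' equal-width bands partitioning 530--725 nm: blue 530--595 nm, green
#' 595--660 nm, red 660--725 nm (band membership by channel center,
#' inclusive bounds). With `scale = TRUE` the result is divided by its
#' maximum and clipped to `[0, 1]` for display.
#'
#' @param cube A `reflectance_cube` whose grid covers 530--725 nm.
#' @param scale Scale to display range.
#' @return `lines x samples x 3` array, channel order R, G, B.
#' @export
pseudocolor_rgb <- function(cube, scale = TRUE) {
  g <- cube$grid
  bands <- list(red = c(660, 725), green = c(595, 660), blue = c(530, 595))
  idx <- lapply(bands, function(b) which(g$centers >= b[1] & g$centers <= b[2]))
  if (any(lengths(idx) == 0))
    stop("spectral grid does not cover the 530-725 nm pseudocolor range",
         call. = FALSE)
  d <- dim(cube$values)
  out <- array(0, c(d[1], d[2], 3))
  for (k in 1:3)
    out[, , k] <- apply(cube$values[, , idx[[k]], drop = FALSE], c(1, 2), mean)
  if (scale) {
    m <- max(out)
    if (m > 0) out <- out / m
    out <- pmin(pmax(out, 0), 1)
  }
  out
}

#' Write / read a hyperspectral cube in an ENVI-style format
#'
#' Plain-text header (`<path>.hdr`: samples, lines, bands, data type 4 =
#' 32-bit float, interleave BSQ, byte order 0, wavelength list in nm) plus a
#' raw little-endian float32 band-sequential binary at `<path>`. The
#' validity mask is stored alongside as `<path>.mask` (uint8, BSQ) and cube
#' metadata as extra `meta.*` header entries, so the round trip is lossless
#' up to float32 for the payload.
#'
#' @param cube A `hyper_cube`.
#' @param path Path of the binary payload (header and mask paths are derived
#'   from it).
#' @return `write_cube` returns `path` invisibly; `read_cube` the cube.
#' @export
write_cube <- function(cube, path) {
  d <- dim(cube$values)
  hdr <- c(
    "ENVI",
    "description = {pushbroom hyperspectral cube}",
    sprintf("samples = %d", d[2]),
    sprintf("lines = %d", d[1]),
    sprintf("bands = %d", d[3]),
    "header offset = 0",
    "file type = ENVI Standard",
    "data type = 4",
    "interleave = bsq",
    "byte order = 0",
    "wavelength units = nm",
    sprintf("kind = %s", sub("_cube$", "", class(cube)[1])),
    paste0("wavelength = {", paste(format(cube$grid$centers, trim = TRUE),
                                   collapse = ", "), "}")
  )
  for (nm in names(cube$meta)) {
    v <- cube$meta[[nm]]
    if (is.null(v) || !length(v)) next
    hdr <- c(hdr, sprintf("meta.%s = {%s}", nm, paste(v, collapse = ", ")))
  }
  writeLines(hdr, paste0(path, ".hdr"))
  con <- file(path, "wb")
  on.exit(close(con))
  # BSQ: samples fastest, then lines, then bands
  writeBin(as.vector(aperm(cube$values, c(2, 1, 3))), con,
           size = 4, endian = "little")
  mcon <- file(paste0(path, ".mask"), "wb")
  writeBin(as.integer(aperm(cube$mask, c(2, 1, 3))), mcon, size = 1)
  close(mcon)
  invisible(path)
}

#' @rdname write_cube
#' @export
read_cube <- function(path) {
  hdr_path <- paste0(path, ".hdr")
  if (!file.exists(hdr_path)) stop("missing header file ", hdr_path, call. = FALSE)
  lines <- readLines(hdr_path)
  val <- function(key, required = TRUE) {
    i <- grep(sprintf("^%s *=", key), lines)
    if (!length(i)) {
      if (required)
        stop(sprintf("malformed ENVI header: missing `%s`", key), call. = FALSE)
      return(NULL)
    }
    sub(sprintf("^%s *= *", key), "", lines[i[1]])
  }
  ns <- as.integer(val("samples")); nl <- as.integer(val("lines"))
  nb <- as.integer(val("bands"))
  if (as.integer(val("data type")) != 4L)
    stop("unsupported ENVI data type (expected 4, float32)", call. = FALSE)
  if (tolower(val("interleave")) != "bsq")
    stop("unsupported interleave (expected bsq)", call. = FALSE)
  wl_i <- grep("^wavelength *= *\\{", lines)
  if (!length(wl_i))
    stop(sprintf("malformed ENVI header at line %d: no wavelength list",
                 length(lines)), call. = FALSE)
  wl_txt <- sub("^wavelength *= *\\{", "", lines[wl_i[1]])
  wl <- as.numeric(strsplit(gsub("\\}", "", wl_txt), ",")[[1]])
  if (length(wl) != nb)
    stop(sprintf("malformed ENVI header at line %d: wavelength list length %d != bands %d",
                 wl_i[1], length(wl), nb), call. = FALSE)
  n <- ns * nl * nb
  vals <- readBin(path, "numeric", n = n, size = 4, endian = "little")
  if (length(vals) != n)
    stop("cube binary shorter than header promises", call. = FALSE)
  values <- aperm(array(vals, c(ns, nl, nb)), c(2, 1, 3))
  mask_path <- paste0(path, ".mask")
  mask <- if (file.exists(mask_path))
    aperm(array(readBin(mask_path, "integer", n = n, size = 1) > 0,
                c(ns, nl, nb)), c(2, 1, 3))
  else array(TRUE, c(nl, ns, nb))
  spacing <- if (nb > 1) wl[2] - wl[1] else 5
  grid <- build_wavelength_grid(nb, wl[1], wl[1] + nb * spacing)
  meta <- list()
  for (ln in grep("^meta\\.", lines, value = TRUE)) {
    key <- sub("^meta\\.([^ =]+) *=.*$", "\\1", ln)
    v <- gsub("[{}]", "", sub("^[^=]+= *", "", ln))
    parts <- trimws(strsplit(v, ",")[[1]])
    nums <- suppressWarnings(as.numeric(parts))
    meta[[key]] <- if (!anyNA(nums)) nums else parts
  }
  kind <- val("kind", required = FALSE) %||% "reflectance"
  new_hyper_cube(values, grid, mask, meta, kind = kind)
}
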