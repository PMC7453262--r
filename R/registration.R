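#' Homography estimation and projective warping
#'
#' A homography is the 3 x 3 projective map between two planes used to
#' overlay the false-color image derived from hyperspectral data on the
#' color-video frame: destination pixel coordinates are
#' `x' = (H11 x + H12 y + H13) / (H31 x + H32 y + H33)`,
#' `y' = (H21 x + H22 y + H23) / (H31 x + H32 y + H33)`.
#' Pixel centers sit at integer coordinates, origin top-left, `x` = column.
#'
#' @name homography
NULL

new_homography <- function(H) {
  H <- matrix(as.numeric(H), 3, 3)
  if (abs(det(H)) < 1e-12) stop("homography is singular", call. = FALSE)
  H <- H / H[3, 3]
  structure(H, class = c("homography", "matrix"))
}

#' @export
print.homography <- function(x, ...) {
  cat("<homography> (H33 = 1)\n")
  print(unclass(x))
  invisible(x)
}

#' Apply a homography to points
#' @param H 3 x 3 homography matrix.
#' @param pts n x 2 matrix of (x, y) coordinates.
#' @return n x 2 matrix of mapped coordinates.
#' @export
apply_homography <- function(H, pts) {
  pts <- rbind(matrix(pts, ncol = 2))
  p <- cbind(pts, 1) %*% t(H)
  p[, 1:2] / p[, 3]
}

# Hartley normalization: translate centroid to origin, scale mean distance
# to sqrt(2); returns the 3x3 similarity
hartley_norm <- function(pts) {
  ctr <- colMeans(pts)
  d <- sqrt(rowSums(sweep(pts, 2, ctr)^2))
  s <- if (mean(d) > 0) sqrt(2) / mean(d) else 1
  matrix(c(s, 0, -s * ctr[1],
           0, s, -s * ctr[2],
           0, 0, 1), 3, 3, byrow = TRUE)
}

# direct linear transform on >= 4 correspondences (normalized least squares)
dlt_homography <- function(src, dst) {
  Ts <- hartley_norm(src); Td <- hartley_norm(dst)
  s <- apply_homography(Ts, src); d <- apply_homography(Td, dst)
  n <- nrow(s)
  A <- matrix(0, 2 * n, 9)
  for (i in seq_len(n)) {
    x <- s[i, 1]; y <- s[i, 2]; u <- d[i, 1]; v <- d[i, 2]
    A[2 * i - 1, ] <- c(-x, -y, -1, 0, 0, 0, u * x, u * y, u)
    A[2 * i, ] <- c(0, 0, 0, -x, -y, -1, v * x, v * y, v)
  }
  # null vector of A: smallest eigenvector of the 9 x 9 normal matrix
  # (works for the 8 x 9 minimal system as well as overdetermined ones)
  h <- eigen(crossprod(A), symmetric = TRUE)$vectors[, 9]
  Hn <- matrix(h, 3, 3, byrow = TRUE)
  H <- solve(Td) %*% Hn %*% Ts
  new_homography(H)
}

any_collinear <- function(pts, tol = 1e-8) {
  n <- nrow(pts)
  cmb <- utils::combn(n, 3)
  for (j in seq_len(ncol(cmb))) {
    p <- pts[cmb[, j], ]
    a <- abs((p[2, 1] - p[1, 1]) * (p[3, 2] - p[1, 2]) -
               (p[3, 1] - p[1, 1]) * (p[2, 2] - p[1, 2]))
    if (a < tol) return(TRUE)
  }
  FALSE
}

#' Robust homography from point correspondences (RANSAC)
#'
#' RANSAC over 4-point minimal samples (degenerate samples with 3 collinear
#' points in either image are rejected), inliers scored by back-projection
#' error below `threshold_px`, followed by a normalized-DLT least-squares
#' refit on all inliers. The device estimates this once from 25 manually
#' annotated point pairs.
#'
#' @param src,dst n x 2 matrices of corresponding (x, y) pixel coordinates,
#'   n >= 4, or a 4-column data frame `(x_src, y_src, x_dst, y_dst)` passed
#'   as `src`.
#' @param threshold_px Inlier back-projection threshold (default 3 px).
#' @param seed Integer seed making the sampling deterministic.
#' @param max_iter Iteration cap (default 2000); iterations also stop
#'   adaptively at `confidence`.
#' @param confidence Desired probability of an outlier-free sample.
#' @return List with `H` (the `homography`), `inliers` (logical), and
#'   `rms` back-projection error over the inliers.
#' @export
estimate_homography <- function(src, dst = NULL, threshold_px = 3, seed = 1L,
                                max_iter = 2000L, confidence = 0.995) {
  if (is.null(dst)) {
    cs <- as.matrix(src)
    src <- cs[, 1:2, drop = FALSE]; dst <- cs[, 3:4, drop = FALSE]
  }
  src <- rbind(matrix(as.numeric(as.matrix(src)), ncol = 2))
  dst <- rbind(matrix(as.numeric(as.matrix(dst)), ncol = 2))
  n <- nrow(src)
  if (n < 4L || nrow(dst) != n)
    stop("estimation failure: need at least 4 correspondence pairs", call. = FALSE)
  if (!all(is.finite(src)) || !all(is.finite(dst)))
    stop("correspondences must be finite", call. = FALSE)
  errs_for <- function(H) {
    proj <- apply_homography(H, src)
    sqrt(rowSums((proj - dst)^2))
  }
  if (n == 4L) {
    if (any_collinear(src) || any_collinear(dst))
      stop("estimation failure: degenerate correspondence set", call. = FALSE)
    H <- dlt_homography(src, dst)
    return(list(H = H, inliers = rep(TRUE, n), rms = sqrt(mean(errs_for(H)^2))))
  }
  best <- NULL; best_n <- -1L
  with_seed(as.integer(seed), {
    needed <- max_iter
    it <- 0L
    while (it < min(needed, max_iter)) {
      it <- it + 1L
      pick <- sample.int(n, 4L)
      if (any_collinear(src[pick, ]) || any_collinear(dst[pick, ])) next
      H <- tryCatch(dlt_homography(src[pick, ], dst[pick, ]),
                    error = function(e) NULL)
      if (is.null(H)) next
      inl <- errs_for(H) < threshold_px
      if (sum(inl) > best_n) {
        best_n <- sum(inl); best <- inl
        w <- max(min(best_n / n, 1 - 1e-12), 1e-12)
        needed <- ceiling(log(1 - confidence) / log(1 - w^4))
      }
    }
  })
  if (is.null(best) || best_n < 4L)
    stop("estimation failure: no sample produced at least 4 inliers", call. = FALSE)
  H <- dlt_homography(src[best, , drop = FALSE], dst[best, , drop = FALSE])
  # refresh the inlier set under the refit model
  inl <- errs_for(H) < threshold_px
  if (sum(inl) >= 4L && !identical(inl, best))
    H <- dlt_homography(src[inl, , drop = FALSE], dst[inl, , drop = FALSE])
  else inl <- best
  list(H = H, inliers = inl, rms = sqrt(mean(errs_for(H)[inl]^2)))
}

#' Warp an image under a homography
#'
#' The homography maps source coordinates to destination coordinates; each
#' output pixel `(x, y)` is therefore sampled from the source image at
#' `H^{-1}(x, y)` with bilinear interpolation (or nearest-neighbor for
#' label/index images, to avoid mixing values). Out-of-bounds samples get
#' `fill` and are marked in the returned mask.
#'
#' @param img Matrix (grayscale) or rows x cols x channels array.
#' @param H A `homography` (source to destination).
#' @param out_shape `c(rows, cols)` of the output (default input shape).
#' @param fill Fill value for unmapped pixels.
#' @param interp `"bilinear"` or `"nearest"`.
#' @return List with `image` and logical `mask` (TRUE where mapped).
#' @export
warp_image <- function(img, H, out_shape = NULL,
                       fill = 0, interp = c("bilinear", "nearest")) {
  interp <- match.arg(interp)
  Hinv <- solve(H)
  multi <- length(dim(img)) == 3L
  d_in <- if (multi) dim(img)[1:2] else dim(img)
  if (is.null(out_shape)) out_shape <- d_in
  nr <- out_shape[1]; nc <- out_shape[2]
  # 0-based pixel-center coordinates; x = column, y = row
  gx <- rep(seq_len(nc) - 1, each = nr)
  gy <- rep(seq_len(nr) - 1, times = nc)
  sp <- apply_homography(Hinv, cbind(gx, gy))
  sx <- sp[, 1]; sy <- sp[, 2]
  sample_plane <- function(plane) {
    out <- rep(fill, nr * nc)
    if (interp == "nearest") {
      ix <- round(sx) + 1; iy <- round(sy) + 1
      ok <- ix >= 1 & ix <= d_in[2] & iy >= 1 & iy <= d_in[1]
      out[ok] <- plane[cbind(iy[ok], ix[ok])]
    } else {
      ok <- sx >= -1e-9 & sx <= d_in[2] - 1 + 1e-9 &
        sy >= -1e-9 & sy <= d_in[1] - 1 + 1e-9
      # clamp so points on the far edges interpolate from the last cell
      x0c <- pmin(pmax(floor(sx[ok]), 0), d_in[2] - 2)
      y0c <- pmin(pmax(floor(sy[ok]), 0), d_in[1] - 2)
      fx <- sx[ok] - x0c; fy <- sy[ok] - y0c
      r0 <- y0c + 1; c0 <- x0c + 1
      v <- plane[cbind(r0, c0)] * (1 - fx) * (1 - fy) +
        plane[cbind(r0, c0 + 1)] * fx * (1 - fy) +
        plane[cbind(r0 + 1, c0)] * (1 - fx) * fy +
        plane[cbind(r0 + 1, c0 + 1)] * fx * fy
      out[ok] <- v
    }
    list(v = out, ok = ok)
  }
  if (multi) {
    out <- array(fill, c(nr, nc, dim(img)[3]))
    ok <- NULL
    for (k in seq_len(dim(img)[3])) {
      r <- sample_plane(img[, , k])
      out[, , k] <- matrix(r$v, nr, nc)
      ok <- r$ok
    }
  } else {
    r <- sample_plane(img)
    out <- matrix(r$v, nr, nc)
    ok <- r$ok
  }
  mask <- matrix(FALSE, nr, nc)
  mask[cbind(gy + 1, gx + 1)] <- ok
  list(image = out, mask = mask)
}

#' Alpha-blend a registered image over a base image
#'
#' `alpha = 0` leaves the base untouched, `alpha = 1` replaces it by the
#' registered image on mask-valid pixels; outside the mask the base is kept.
#'
#' @param base,registered Images of identical shape (matrix or 3-channel
#'   array).
#' @param alpha Blend weight in `[0, 1]`.
#' @param mask Logical matrix of valid registered pixels (default all).
#' @return Blended image.
#' @export
overlay_images <- function(base, registered, alpha = 0.5, mask = NULL) {
  if (!identical(dim(base), dim(registered)))
    stop("`base` and `registered` must have identical shape", call. = FALSE)
  stopifnot(alpha >= 0, alpha <= 1)
  d2 <- if (length(dim(base)) == 3L) dim(base)[1:2] else dim(base)
  if (is.null(mask)) mask <- matrix(TRUE, d2[1], d2[2])
  m <- if (length(dim(base)) == 3L) array(mask, dim(base)) else mask
  out <- base
  out[m] <- (1 - alpha) * base[m] + alpha * registered[m]
  out
}

#' Read / write point correspondences and homographies as text
#'
#' Correspondences as CSV with columns `x_src, y_src, x_dst, y_dst`;
#' homographies as a plain 3 x 3 whitespace-separated matrix.
#'
#' @param path File path.
#' @param cs Data frame of correspondences.
#' @param H A `homography`.
#' @export
read_correspondences <- function(path) {
  cs <- utils::read.csv(path)
  need <- c("x_src", "y_src", "x_dst", "y_dst")
  if (!all(need %in% names(cs)))
    stop("correspondence CSV must have columns x_src, y_src, x_dst, y_dst",
         call. = FALSE)
  cs[need]
}

#' @rdname read_correspondences
#' @export
write_correspondences <- function(cs, path) {
  utils::write.csv(cs, path, row.names = FALSE)
  invisible(path)
}

#' @rdname read_correspondences
#' @export
write_homography <- function(H, path) {
  writeLines(apply(format(unclass(H), digits = 17), 1, paste, collapse = " "),
             path)
  invisible(path)
}

#' @rdname read_correspondences
#' @export
read_homography <- function(path) {
  rows <- lapply(readLines(path), function(l)
    as.numeric(strsplit(trimws(l), " +")[[1]]))
  new_homography(do.call(rbind, rows))
}
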