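# Internal numeric helpers shared across modules.
#
# Project-wide coordinate convention: 0-based, x = column, y = row, pixel
# centers at integer coordinates. Internal R arrays are 1-based; every helper
# below takes and returns the 0-based convention.

#' Bilinear interpolation at sub-pixel coordinates
#'
#' Samples a 2D image at arbitrary (x, y) positions using bilinear
#' interpolation. Coordinates are 0-based with pixel centers at integers;
#' integer coordinates therefore return exact pixel values.
#'
#' @param img numeric matrix (rows = y, cols = x).
#' @param x,y numeric vectors of equal length, 0-based coordinates. Must lie
#'   inside `[0, ncol-1] x [0, nrow-1]`.
#' @return numeric vector of interpolated intensities.
#' @keywords internal
bilinear_sample <- function(img, x, y) {
  h <- nrow(img); w <- ncol(img)
  if (any(x < 0 | x > w - 1 | y < 0 | y > h - 1)) {
    stop("bilinear_sample: coordinates outside image bounds")
  }
  # clamp the base index so x = w-1 uses the last pixel pair with weight 1
  ix <- pmin(floor(x), w - 2L)
  iy <- pmin(floor(y), h - 2L)
  fx <- x - ix
  fy <- y - iy
  i11 <- cbind(iy + 1, ix + 1)
  i12 <- cbind(iy + 1, ix + 2)
  i21 <- cbind(iy + 2, ix + 1)
  i22 <- cbind(iy + 2, ix + 2)
  img[i11] * (1 - fx) * (1 - fy) + img[i12] * fx * (1 - fy) +
    img[i21] * (1 - fx) * fy + img[i22] * fx * fy
}

# 2D convolution with edge-replicate padding, vectorised over kernel offsets.
# kernel must be odd-sized square; adequate for the small PSF-scale kernels
# used in spot detection.
conv2_replicate <- function(img, kernel) {
  r <- (nrow(kernel) - 1L) %/% 2L
  h <- nrow(img); w <- ncol(img)
  pad <- matrix(0, h + 2L * r, w + 2L * r)
  pad[(r + 1):(r + h), (r + 1):(r + w)] <- img
  # replicate edges
  pad[1:r, (r + 1):(r + w)] <- matrix(img[1, ], r, w, byrow = TRUE)
  pad[(r + h + 1):(h + 2 * r), (r + 1):(r + w)] <- matrix(img[h, ], r, w, byrow = TRUE)
  pad[, 1:r] <- pad[, r + 1]
  pad[, (r + w + 1):(w + 2 * r)] <- pad[, r + w]
  out <- matrix(0, h, w)
  for (di in seq_len(2L * r + 1L)) {
    for (dj in seq_len(2L * r + 1L)) {
      k <- kernel[di, dj]
      if (k != 0) out <- out + k * pad[(di):(di + h - 1L), (dj):(dj + w - 1L)]
    }
  }
  out
}

# Scale-normalised, sign-flipped Laplacian-of-Gaussian kernel: bright blobs of
# scale sigma give a positive peak. Zero-sum so flat regions respond exactly 0.
log_kernel <- function(sigma) {
  r <- max(2L, as.integer(ceiling(3.5 * sigma)))
  ax <- (-r):r
  g <- outer(ax, ax, function(y, x) exp(-(x^2 + y^2) / (2 * sigma^2)))
  lap <- outer(ax, ax, function(y, x) (x^2 + y^2 - 2 * sigma^2) / sigma^2)
  k <- -lap * g
  k - mean(k)
}

# fraction of a unit-integral 1D Gaussian (mean mu, sd sigma) falling inside
# the pixel centred at integer c (i.e. [c-0.5, c+0.5])
gauss_pixel_frac <- function(centers, mu, sigma) {
  stats::pnorm((centers + 0.5 - mu) / sigma) - stats::pnorm((centers - 0.5 - mu) / sigma)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
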