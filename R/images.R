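#' @title Low-level image primitives
#' @description Separable Gaussian smoothing and binary morphology with
#'   explicit structuring elements. Intensity images are plain numeric
#'   matrices on an 8-bit scale (0-255); binary masks are logical matrices.
#' @name image-primitives
NULL

#' Discrete Gaussian kernel
#'
#' Truncated, normalised 1D Gaussian used by [gaussian_smooth()]. The kernel
#' is cut at `radius` (default 4 standard deviations), matching common
#' scientific-imaging practice.
#'
#' @param sigma standard deviation in pixels (> 0).
#' @param radius half-width of the kernel in pixels.
#' @return numeric vector of length `2 * radius + 1` summing to 1.
#' @export
gaussian_kernel <- function(sigma, radius = ceiling(4 * sigma)) {
  stopifnot(sigma > 0, radius >= 1)
  x <- (-radius):radius
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# Banded convolution matrix with reflect boundary handling
# (reflect: ... c b a | a b c ... ; the scheme used by scipy.ndimage).
conv_band_matrix <- function(n, k) {
  r <- (length(k) - 1L) / 2L
  M <- matrix(0, n, n)
  for (o in -r:r) {
    j <- seq_len(n) + o
    j[j < 1L] <- 1L - j[j < 1L]
    j[j > n] <- 2L * n + 1L - j[j > n]
    idx <- cbind(seq_len(n), j)
    M[idx] <- M[idx] + k[o + r + 1L]
  }
  M
}

#' Gaussian smoothing of a grayscale image
#'
#' Separable convolution with a truncated Gaussian and reflecting boundaries;
#' a constant image is returned unchanged and the global mean is preserved up
#' to floating-point rounding.
#'
#' @param image numeric matrix.
#' @param sigma standard deviation of the Gaussian in pixels.
#' @return numeric matrix of the same shape.
#' @export
gaussian_smooth <- function(image, sigma) {
  stopifnot(is.matrix(image), sigma > 0)
  if (nrow(image) == 0L || ncol(image) == 0L) stop("empty image")
  k <- gaussian_kernel(sigma)
  Kr <- conv_band_matrix(nrow(image), k)
  Kc <- conv_band_matrix(ncol(image), k)
  Kr %*% image %*% t(Kc)
}

# out[i, j] <- m[i + dr, j + dc], with `fill` outside the domain.
shift_mat <- function(m, dr, dc, fill = 0) {
  H <- nrow(m); W <- ncol(m)
  out <- matrix(fill, H, W)
  i <- max(1L, 1L - dr):min(H, H - dr)
  j <- max(1L, 1L - dc):min(W, W - dc)
  if (length(i) > 0L && length(j) > 0L && i[1] <= i[length(i)] && j[1] <= j[length(j)])
    out[i, j] <- m[i + dr, j + dc]
  out
}

#' Structuring elements
#'
#' `se_square(n)` is the full n-by-n square. `se_cross2()` is the 2x2 cross
#' and `se_ellipse4()` the 4x4 ellipse used when merging nearby components
#' before graph extraction. Even-sized elements have no natural centre; all
#' morphology here anchors them at the top-left pixel of the central 2x2
#' core (see [default_anchor()]), and the exact footprints are:
#'
#' ```
#' se_cross2():  1 1      se_ellipse4():  0 1 1 0
#'               1 0                      1 1 1 1
#'                                        1 1 1 1
#'                                        0 1 1 0
#' ```
#'
#' @param n side length of the square element.
#' @return logical matrix footprint.
#' @export
se_square <- function(n) matrix(TRUE, n, n)

#' @rdname se_square
#' @export
se_cross2 <- function() matrix(c(TRUE, TRUE, TRUE, FALSE), 2, 2, byrow = TRUE)

#' @rdname se_square
#' @export
se_ellipse4 <- function() {
  matrix(c(0, 1, 1, 0,
           1, 1, 1, 1,
           1, 1, 1, 1,
           0, 1, 1, 0) == 1, 4, 4, byrow = TRUE)
}

#' Default anchor of a structuring element
#'
#' Centre pixel for odd sizes; top-left pixel of the central 2x2 core for
#' even sizes (so a 2x2 element anchors at its (1,1) pixel).
#'
#' @param fp logical matrix footprint.
#' @return integer vector `c(row, col)`.
#' @export
default_anchor <- function(fp) {
  c(floor((nrow(fp) - 1L) / 2L) + 1L, floor((ncol(fp) - 1L) / 2L) + 1L)
}

#' Binary morphology
#'
#' Dilation, erosion and closing of logical masks by an arbitrary footprint.
#' Dilation treats pixels outside the image as background; the erosion used
#' inside [close_mask()] is the adjoint erosion (outside treated as
#' foreground), which makes closing extensive and idempotent.
#'
#' @param mask logical matrix.
#' @param fp logical matrix footprint (see [se_square()]).
#' @param anchor anchor position within the footprint.
#' @param pad value assumed outside the image during erosion.
#' @return logical matrix of the same shape.
#' @export
dilate_mask <- function(mask, fp, anchor = default_anchor(fp)) {
  stopifnot(is.matrix(mask))
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  idx <- which(fp, arr.ind = TRUE)
  for (k in seq_len(nrow(idx))) {
    out <- out | shift_mat(mask, -(idx[k, 1L] - anchor[1L]), -(idx[k, 2L] - anchor[2L]), FALSE)
  }
  out
}

#' @rdname dilate_mask
#' @export
erode_mask <- function(mask, fp, anchor = default_anchor(fp), pad = TRUE) {
  stopifnot(is.matrix(mask))
  out <- matrix(TRUE, nrow(mask), ncol(mask))
  idx <- which(fp, arr.ind = TRUE)
  for (k in seq_len(nrow(idx))) {
    out <- out & shift_mat(mask, idx[k, 1L] - anchor[1L], idx[k, 2L] - anchor[2L], pad)
  }
  out
}

#' @rdname dilate_mask
#' @export
close_mask <- function(mask, fp, anchor = default_anchor(fp)) {
  erode_mask(dilate_mask(mask, fp, anchor), fp, anchor, pad = TRUE)
}

#' @rdname dilate_mask
#' @export
open_mask <- function(mask, fp, anchor = default_anchor(fp)) {
  dilate_mask(erode_mask(mask, fp, anchor, pad = FALSE), fp, anchor)
}

# Dilate a set of pixel coordinates (matrix [i, j]) by all offsets of a
# (2r+1)-square, clipping to the image; returns unique linear indices.
grow_pixel_set <- function(ij, r, H, W) {
  if (nrow(ij) == 0L) return(integer(0))
  offs <- expand.grid(di = -r:r, dj = -r:r)
  i <- rep(ij[, 1L], times = nrow(offs)) + rep(offs$di, each = nrow(ij))
  j <- rep(ij[, 2L], times = nrow(offs)) + rep(offs$dj, each = nrow(ij))
  keep <- i >= 1L & i <= H & j >= 1L & j <= W
  unique((j[keep] - 1L) * H + i[keep])
}

# Sobel gradients (3x3); returns list(gx, gy) with gx the horizontal
# derivative (columns) and gy the vertical derivative (rows).
sobel_gradients <- function(image) {
  s <- function(dr, dc) shift_mat(image, dr, dc, 0)
  # replicate borders so edge responses are not inflated at the frame
  H <- nrow(image); W <- ncol(image)
  pad <- rbind(image[1L, , drop = FALSE], image, image[H, , drop = FALSE])
  pad <- cbind(pad[, 1L, drop = FALSE], pad, pad[, W, drop = FALSE])
  p <- function(dr, dc) pad[(2L + dr):(H + 1L + dr), (2L + dc):(W + 1L + dc)]
  gx <- (p(-1L, 1L) + 2 * p(0L, 1L) + p(1L, 1L)) - (p(-1L, -1L) + 2 * p(0L, -1L) + p(1L, -1L))
  gy <- (p(1L, -1L) + 2 * p(1L, 0L) + p(1L, 1L)) - (p(-1L, -1L) + 2 * p(-1L, 0L) + p(-1L, 1L))
  list(gx = gx, gy = gy)
}
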