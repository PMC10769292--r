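#' Thresholding pipeline configuration
#'
#' Parameters of the two non-learning segmentation pipelines (Otsu-core and
#' Canny-core). The shared stages are a Gaussian pre-filter (`gaussian_sigma`),
#' a binary split at `split_threshold` into osteocyte and dendrite candidate
#' masks, a second noise threshold on the dendrite candidate, the core
#' operator, a morphological closing of the dendrite mask and an elementwise
#' subtraction of the osteocyte mask. All thresholds are on the 8-bit scale.
#'
#' @param gaussian_sigma pre-filter standard deviation in pixels.
#' @param split_threshold foreground threshold separating tissue from matrix.
#' @param dendrite_noise_threshold second threshold suppressing faint pixels
#'   in the dendrite candidate.
#' @param canny_low,canny_high Canny hysteresis thresholds on the L1 Sobel
#'   gradient magnitude.
#' @param otsu_low,otsu_high histogram range restriction for the Otsu core.
#' @param closing_kernel side of the square closing element.
#' @param min_soma_area minimum area (px) of an osteocyte candidate blob.
#' @param soma_opening side of the square opening element that separates
#'   thick somas from thin processes at the candidate-split stage.
#' @return an object of class `threshold_config`.
#' @export
threshold_config <- function(gaussian_sigma = 2, split_threshold = 70,
                             dendrite_noise_threshold = 78,
                             canny_low = 70, canny_high = 220,
                             otsu_low = 80, otsu_high = 255,
                             closing_kernel = 3L, min_soma_area = 30L,
                             soma_opening = 5L) {
  stopifnot(gaussian_sigma > 0,
            split_threshold >= 0, split_threshold <= 255,
            dendrite_noise_threshold >= 0, dendrite_noise_threshold <= 255,
            canny_low < canny_high,
            otsu_low >= 0, otsu_high <= 255, otsu_low < otsu_high,
            closing_kernel >= 1, min_soma_area >= 0, soma_opening >= 1)
  structure(list(gaussian_sigma = gaussian_sigma,
                 split_threshold = split_threshold,
                 dendrite_noise_threshold = dendrite_noise_threshold,
                 canny_low = canny_low, canny_high = canny_high,
                 otsu_low = otsu_low, otsu_high = otsu_high,
                 closing_kernel = as.integer(closing_kernel),
                 min_soma_area = as.integer(min_soma_area),
                 soma_opening = as.integer(soma_opening)),
            class = "threshold_config")
}

#' Pre-filter an image for thresholding
#'
#' Gaussian noise reduction (reflecting boundaries); the global mean is
#' preserved up to rounding. Images on a 16-bit scale (max > 255) are first
#' rescaled to 8 bits by max-normalisation so the fixed thresholds apply.
#'
#' @param image numeric matrix.
#' @param sigma Gaussian standard deviation in pixels.
#' @return smoothed numeric matrix, same shape.
#' @export
preprocess_image <- function(image, sigma = 2) {
  stopifnot(is.matrix(image))
  if (length(image) == 0L) stop("empty image")
  mx <- max(image)
  if (mx > 255) image <- image / mx * 255
  gaussian_smooth(image, sigma)
}

#' Split a pre-filtered image into osteocyte and dendrite candidates
#'
#' Pixels at or above `split_threshold` are tissue foreground. The osteocyte
#' candidate is the morphological opening of the foreground by a
#' `soma_opening`-square (which removes structures thinner than the element,
#' i.e. canalicular processes) with blobs under `min_soma_area` px dropped;
#' the dendrite candidate is the remaining foreground with pixels below
#' `dendrite_noise_threshold` suppressed. The two candidates are disjoint by
#' construction.
#'
#' @param image pre-filtered numeric matrix.
#' @param cfg a [threshold_config()].
#' @return list of logical matrices `osteo` and `dend`.
#' @export
split_candidate_masks <- function(image, cfg = threshold_config()) {
  stopifnot(is.matrix(image), inherits(cfg, "threshold_config"))
  fg <- image >= cfg$split_threshold
  opened <- open_mask(fg, se_square(cfg$soma_opening))
  # the split threshold sits far below soma intensity, so the opened mask
  # carries the blur ring around each soma; an Otsu cut on the opened
  # region's own histogram lands at half-contrast, i.e. the soma boundary
  osteo <- opened
  if (any(opened)) {
    t_soma <- tryCatch(
      otsu_threshold(image[opened], cfg$split_threshold, 255),
      error = function(e) NA_integer_)
    if (!is.na(t_soma)) {
      core <- opened & round(image) >= t_soma
      # the half-contrast level sits ~1 px inside small convex somas
      # (curvature bias of the blur); one dilation step compensates
      osteo <- opened & dilate_mask(core, se_square(3L))
    }
  }
  if (cfg$min_soma_area > 0L && any(osteo)) {
    cc <- connected_components(osteo, 8)
    sizes <- tabulate(cc[cc > 0L])
    keep <- which(sizes >= cfg$min_soma_area)
    osteo <- matrix(cc %in% keep & cc > 0L, nrow(image), ncol(image))
  }
  dend <- fg & !opened & image >= cfg$dendrite_noise_threshold
  list(osteo = osteo, dend = dend)
}

# Otsu threshold over the integer histogram of `values` restricted to
# [lo, hi]: the smallest t maximising between-class variance of the split
# [lo, t-1] vs [t, hi]. Returns NA when no pixel falls inside the range.
otsu_threshold <- function(values, lo, hi) {
  v <- round(values)
  v <- v[v >= lo & v <= hi]
  if (length(v) == 0L) return(NA_integer_)
  if (length(unique(v)) < 2L)
    stop("degenerate histogram: fewer than two distinct intensities in [lo, hi]")
  levels <- lo:hi
  h <- tabulate(v - lo + 1L, nbins = length(levels))
  n <- sum(h)
  cum_n <- cumsum(h)
  cum_s <- cumsum(h * levels)
  # split at t: background = [lo, t-1] -> counts cum at index (t-1-lo+1)
  ts <- (lo + 1L):hi
  n0 <- cum_n[ts - lo]
  s0 <- cum_s[ts - lo]
  n1 <- n - n0
  w0 <- n0 / n; w1 <- n1 / n
  mu0 <- ifelse(n0 > 0, s0 / n0, 0)
  mu1 <- ifelse(n1 > 0, (cum_s[length(levels)] - s0) / n1, 0)
  sb <- ifelse(n0 > 0 & n1 > 0, w0 * w1 * (mu0 - mu1)^2, -Inf)
  ts[which.max(sb)]
}

#' Otsu core operator with histogram-range restriction
#'
#' Chooses the threshold maximising between-class variance over the image
#' histogram restricted to `[lo, hi]` and returns the foreground mask
#' (pixels at or above the threshold). An image with no pixel in the range
#' yields an empty mask; a constant in-range histogram is an error.
#'
#' @param image numeric matrix.
#' @param lo,hi histogram range restriction (8-bit scale).
#' @return logical matrix with attribute `threshold`.
#' @export
otsu_core <- function(image, lo = 80, hi = 255) {
  stopifnot(is.matrix(image), lo < hi)
  t <- otsu_threshold(image, lo, hi)
  if (is.na(t)) {
    out <- matrix(FALSE, nrow(image), ncol(image))
    attr(out, "threshold") <- NA_integer_
    return(out)
  }
  out <- round(image) >= t
  attr(out, "threshold") <- t
  out
}

#' Canny core operator
#'
#' Classic hysteresis edge detection: 3x3 Sobel derivatives, L1 gradient
#' magnitude, non-maximum suppression along the quantised gradient
#' direction, then hysteresis (pixels >= `high` seed edges; pixels >= `low`
#' are kept when 8-connected to a seed). The caller is expected to have
#' smoothed the image already (shared pre-processing stage).
#'
#' @param image numeric matrix.
#' @param low,high hysteresis thresholds, `low < high`.
#' @return logical edge mask.
#' @export
canny_core <- function(image, low = 70, high = 220) {
  stopifnot(is.matrix(image), low < high)
  g <- sobel_gradients(image)
  mag <- abs(g$gx) + abs(g$gy)
  if (all(mag < low)) return(matrix(FALSE, nrow(image), ncol(image)))
  ang <- atan2(g$gy, g$gx)
  # quantise direction to 0/45/90/135 degrees
  sector <- (round(ang / (pi / 4)) %% 4)
  s <- function(dr, dc) shift_mat(mag, dr, dc, 0)
  keep <- matrix(FALSE, nrow(image), ncol(image))
  nbr <- list(`0` = list(c(0L, 1L), c(0L, -1L)),     # horizontal gradient
              `1` = list(c(1L, 1L), c(-1L, -1L)),    # 45 degrees
              `2` = list(c(1L, 0L), c(-1L, 0L)),     # vertical gradient
              `3` = list(c(1L, -1L), c(-1L, 1L)))    # 135 degrees
  for (sec in 0:3) {
    a <- s(nbr[[sec + 1L]][[1L]][1L], nbr[[sec + 1L]][[1L]][2L])
    b <- s(nbr[[sec + 1L]][[2L]][1L], nbr[[sec + 1L]][[2L]][2L])
    keep <- keep | (sector == sec & mag >= a & mag >= b)
  }
  weak <- keep & mag >= low
  strong <- keep & mag >= high
  if (!any(strong)) return(matrix(FALSE, nrow(image), ncol(image)))
  cc <- connected_components(weak, 8)
  seeds <- unique(cc[strong])
  seeds <- seeds[seeds > 0L]
  matrix(cc %in% seeds & cc > 0L, nrow(image), ncol(image))
}

#' Post-process candidate masks into the final label
#'
#' Morphological closing of the dendrite mask (square `closing_kernel`)
#' followed by elementwise subtraction of the osteocyte mask, yielding a
#' three-class label with mutually exclusive classes.
#'
#' @param osteo,dend logical matrices of equal shape.
#' @param closing_kernel side of the square closing element.
#' @return integer label matrix (0 background, 1 osteocyte, 2 dendrite).
#' @export
postprocess_label <- function(osteo, dend, closing_kernel = 3L) {
  if (!is.matrix(osteo) || !is.matrix(dend) || !all(dim(osteo) == dim(dend)))
    stop("shape mismatch between osteocyte and dendrite masks")
  dend2 <- close_mask(dend, se_square(closing_kernel)) & !osteo
  label <- matrix(0L, nrow(osteo), ncol(osteo))
  label[dend2] <- 2L
  label[osteo] <- 1L
  label
}

#' Threshold-based LCN segmentation
#'
#' Full pipeline: [preprocess_image()] -> [split_candidate_masks()] -> core
#' operator on the dendrite candidate -> [postprocess_label()]. With
#' `method = "otsu"` the core threshold is computed on the histogram of
#' dendrite-candidate pixels clipped to `[otsu_low, otsu_high]` (computing
#' it on the whole image would place the threshold between the dendrite and
#' soma intensity modes); with `method = "canny"` edges are detected on the
#' smoothed image and intersected with the 3x3-dilated dendrite candidate
#' (edge responses flank thin ridges). Deterministic.
#'
#' @param image numeric matrix (8- or 16-bit scale).
#' @param method `"otsu"` or `"canny"`.
#' @param cfg a [threshold_config()].
#' @return integer label matrix (0/1/2).
#' @export
segment_lcn <- function(image, method = c("otsu", "canny"),
                        cfg = threshold_config()) {
  method <- match.arg(method)
  sm <- preprocess_image(image, cfg$gaussian_sigma)
  cand <- split_candidate_masks(sm, cfg)
  dend <- if (method == "otsu") {
    vals <- sm[cand$dend]
    t <- if (length(vals) > 0L && length(unique(round(pmin(pmax(vals, 0), 255)))) >= 2L)
      tryCatch(otsu_threshold(vals, cfg$otsu_low, cfg$otsu_high),
               error = function(e) NA_integer_)
    else NA_integer_
    if (is.na(t)) cand$dend else cand$dend & round(sm) >= t
  } else {
    edges <- canny_core(sm, cfg$canny_low, cfg$canny_high)
    edges & dilate_mask(cand$dend, se_square(3L))
  }
  postprocess_label(cand$osteo, dend, cfg$closing_kernel)
}
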