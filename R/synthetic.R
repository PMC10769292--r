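#' Configuration for a synthetic LCN scene
#'
#' Describes a confocal-style field of view containing bright elliptical
#' osteocyte somas connected by thin curved dendritic processes, with
#' additive noise and an illumination ramp. All intensities are on the 8-bit
#' scale. The defaults emulate phalloidin-stained cryosection scans: somas
#' and processes are near-saturated against a dark matrix, processes are
#' 1.5-3 px wide, and each field holds a handful of cells.
#'
#' @param image_height,image_width field size in pixels.
#' @param n_osteocytes number of somas to place.
#' @param osteocyte_axes_range min/max soma semi-axes in pixels.
#' @param connection_probability probability that a candidate soma pair
#'   (centroids within `connection_radius`) is joined by a dendrite.
#' @param connection_radius maximum centroid distance (px) for candidate
#'   connections; shrinking it shortens the planted connections.
#' @param dead_end_rate expected number of blunted (dead-end) processes per
#'   soma (Poisson).
#' @param dead_end_length_range min/max length (px) of dead-end stubs.
#' @param dendrite_width_range min/max rendered process width in pixels.
#' @param dendrite_waviness curvature amplitude of the quadratic Bezier
#'   paths, as a fraction of the chord length.
#' @param soma_intensity,dendrite_intensity,background_intensity 8-bit
#'   intensity levels of the three tissue classes.
#' @param noise_sd standard deviation of additive Gaussian noise.
#' @param illumination_gradient fractional intensity drop from the left to
#'   the right edge of the field.
#' @param um_per_px pixel calibration in micrometres.
#' @param seed integer RNG seed; scenes are byte-identical for equal seeds.
#' @return an object of class `scene_config` (a named list).
#' @export
scene_config <- function(image_height = 320L, image_width = 320L,
                         n_osteocytes = 16L,
                         osteocyte_axes_range = c(5, 10),
                         connection_probability = 0.9,
                         connection_radius = 120,
                         dead_end_rate = 1.5,
                         dead_end_length_range = c(8, 20),
                         dendrite_width_range = c(1.5, 3),
                         dendrite_waviness = 0.15,
                         soma_intensity = 235,
                         dendrite_intensity = 230,
                         background_intensity = 15,
                         noise_sd = 5,
                         illumination_gradient = 0.1,
                         um_per_px = 0.284,
                         seed = 1L) {
  cfg <- list(
    image_height = as.integer(image_height), image_width = as.integer(image_width),
    n_osteocytes = as.integer(n_osteocytes),
    osteocyte_axes_range = as.numeric(osteocyte_axes_range),
    connection_probability = connection_probability,
    connection_radius = connection_radius,
    dead_end_rate = dead_end_rate,
    dead_end_length_range = as.numeric(dead_end_length_range),
    dendrite_width_range = as.numeric(dendrite_width_range),
    dendrite_waviness = dendrite_waviness,
    soma_intensity = soma_intensity,
    dendrite_intensity = dendrite_intensity,
    background_intensity = background_intensity,
    noise_sd = noise_sd,
    illumination_gradient = illumination_gradient,
    um_per_px = um_per_px,
    seed = as.integer(seed))
  class(cfg) <- "scene_config"
  validate_scene_config(cfg)
  cfg
}

#' Validate a scene configuration
#'
#' @param cfg a `scene_config`.
#' @return `cfg`, invisibly; errors on an invalid field.
#' @export
validate_scene_config <- function(cfg) {
  stopifnot(
    cfg$image_height >= 8L, cfg$image_width >= 8L,
    cfg$n_osteocytes >= 0L,
    length(cfg$osteocyte_axes_range) == 2L,
    cfg$osteocyte_axes_range[1] > 0,
    cfg$osteocyte_axes_range[1] <= cfg$osteocyte_axes_range[2],
    cfg$connection_probability >= 0, cfg$connection_probability <= 1,
    cfg$connection_radius > 0,
    cfg$dead_end_rate >= 0,
    cfg$dendrite_width_range[1] >= 1,
    cfg$dendrite_width_range[1] <= cfg$dendrite_width_range[2],
    cfg$dendrite_waviness >= 0,
    all(c(cfg$soma_intensity, cfg$dendrite_intensity, cfg$background_intensity) >= 0),
    all(c(cfg$soma_intensity, cfg$dendrite_intensity, cfg$background_intensity) <= 255),
    cfg$noise_sd >= 0,
    cfg$illumination_gradient >= 0, cfg$illumination_gradient < 1,
    cfg$um_per_px > 0)
  invisible(cfg)
}

#' Derive an "aged" configuration from a "young" one
#'
#' Applies the degeneration reported for aged bone to a scene configuration:
#' fewer osteocytes, a lower connection probability, shorter connections
#' (via a smaller connection radius) and more dead-end processes, all
#' monotonically in `severity`. At `severity = 1` the osteocyte count is
#' halved and the dead-end rate doubled.
#'
#' @param cfg a `scene_config` describing the young phenotype.
#' @param severity degeneration fraction in \[0, 1\].
#' @return a new `scene_config`.
#' @export
degrade_to_aged <- function(cfg, severity = 1) {
  stopifnot(inherits(cfg, "scene_config"), severity >= 0, severity <= 1)
  if (severity == 0) return(cfg)
  out <- cfg
  out$n_osteocytes <- as.integer(round(cfg$n_osteocytes * (1 - 0.5 * severity)))
  out$connection_probability <- cfg$connection_probability * (1 - 0.15 * severity)
  out$connection_radius <- cfg$connection_radius * (1 - 0.45 * severity)
  out$dead_end_rate <- cfg$dead_end_rate * (1 + severity)
  validate_scene_config(out)
  out
}

# Radius of a rotated ellipse (semi-axes a, b, orientation theta) along the
# absolute direction phi, measured from the centre.
ellipse_radius <- function(a, b, theta, phi) {
  ca <- cos(phi - theta); sa <- sin(phi - theta)
  a * b / sqrt((b * ca)^2 + (a * sa)^2)
}

# Pixels (arr.ind matrix) of a filled rotated ellipse, clipped to the image.
ellipse_pixels <- function(cy, cx, a, b, theta, H, W) {
  r <- ceiling(max(a, b)) + 1L
  ii <- max(1L, floor(cy - r)):min(H, ceiling(cy + r))
  jj <- max(1L, floor(cx - r)):min(W, ceiling(cx + r))
  g <- expand.grid(i = ii, j = jj)
  dx <- g$j - cx; dy <- g$i - cy
  xr <- dx * cos(theta) + dy * sin(theta)
  yr <- -dx * sin(theta) + dy * cos(theta)
  keep <- (xr / a)^2 + (yr / b)^2 <= 1
  cbind(g$i[keep], g$j[keep])
}

# Sample a quadratic Bezier p0 -> p1 with control point c0; returns a dense
# polyline (two-column matrix x = col, y = row) and its arc length.
bezier_polyline <- function(p0, c0, p1, spacing = 0.25) {
  chord <- sqrt(sum((p1 - p0)^2))
  n <- max(8L, ceiling(chord / spacing) * 2L)
  t <- seq(0, 1, length.out = n)
  x <- (1 - t)^2 * p0[1] + 2 * t * (1 - t) * c0[1] + t^2 * p1[1]
  y <- (1 - t)^2 * p0[2] + 2 * t * (1 - t) * c0[2] + t^2 * p1[2]
  cbind(x, y)
}

polyline_length <- function(pl) {
  if (nrow(pl) < 2L) return(0)
  sum(sqrt(diff(pl[, 1])^2 + diff(pl[, 2])^2))
}

# Rasterise a polyline with a given stroke width: pixel centres within
# width/2 of any sample point. Returns arr.ind matrix.
stroke_pixels <- function(pl, width, H, W) {
  r <- width / 2
  ri <- ceiling(r + 0.5)
  offs <- expand.grid(di = -ri:ri, dj = -ri:ri)
  n <- nrow(pl); m <- nrow(offs)
  px <- rep(round(pl[, 1]), times = m) + rep(offs$dj, each = n)
  py <- rep(round(pl[, 2]), times = m) + rep(offs$di, each = n)
  sx <- rep(pl[, 1], times = m)
  sy <- rep(pl[, 2], times = m)
  keep <- (px - sx)^2 + (py - sy)^2 <= r^2 & px >= 1 & px <= W & py >= 1 & py <= H
  if (!any(keep)) return(matrix(integer(0), 0L, 2L))
  ij <- unique(cbind(as.integer(py[keep]), as.integer(px[keep])))
  ij
}

#' Additive noise and illumination ramp
#'
#' Applies, in order, a multiplicative linear illumination ramp (full
#' intensity at the left edge falling to `1 - illumination_gradient` at the
#' right edge, so the left/right column-mean ratio is
#' `1 / (1 - illumination_gradient)`) and additive zero-mean Gaussian noise,
#' then clips to \[0, 255\]. With `noise_sd = 0` and
#' `illumination_gradient = 0` the image is returned unchanged.
#'
#' @param image numeric matrix on the 8-bit scale.
#' @param noise_sd standard deviation of the additive noise.
#' @param illumination_gradient fractional intensity drop across the field.
#' @param seed optional integer; when given, the noise draw is seeded and
#'   the caller's RNG state is left untouched.
#' @return numeric matrix of the same shape.
#' @export
apply_noise <- function(image, noise_sd = 0, illumination_gradient = 0, seed = NULL) {
  stopifnot(is.matrix(image), noise_sd >= 0,
            illumination_gradient >= 0, illumination_gradient < 1)
  if (noise_sd == 0 && illumination_gradient == 0) return(image)
  out <- image
  W <- ncol(out)
  if (illumination_gradient > 0 && W > 1L) {
    ramp <- 1 - illumination_gradient * (seq_len(W) - 1) / (W - 1)
    out <- sweep(out, 2L, ramp, `*`)
  }
  add_noise <- function(m) {
    if (noise_sd > 0) m <- m + stats::rnorm(length(m), 0, noise_sd)
    m
  }
  out <- if (!is.null(seed)) withr::with_seed(as.integer(seed), add_noise(out)) else add_noise(out)
  pmin(pmax(out, 0), 255)
}

#' Generate a synthetic LCN scene with exact ground truth
#'
#' Places non-overlapping elliptical somas, joins sampled soma pairs with
#' quadratic Bezier dendrites of the configured width, adds dead-end stubs,
#' and renders image plus three-class label mask (0 background, 1 osteocyte,
#' 2 dendrite). Rendered dendritic pieces are kept spatially separated from
#' one another and from non-endpoint somas, so on the noise-free mask every
#' planted edge and stub is exactly one dendrite component; the planted
#' graph records what was actually rendered. Output is deterministic in
#' `cfg$seed`.
#'
#' @param cfg a [scene_config()].
#' @param render if `FALSE`, skip image/mask assembly and return only the
#'   planted graph (fast path for topology-level simulations).
#' @return an object of class `lcn_scene`: list with `image`, `mask`,
#'   `graph` (an `lcn_graph`, see [build_graph()]) and `config`.
#' @export
generate_scene <- function(cfg, render = TRUE) {
  validate_scene_config(cfg)
  withr::with_seed(cfg$seed, generate_scene_impl(cfg, render))
}

generate_scene_impl <- function(cfg, render) {
  H <- cfg$image_height; W <- cfg$image_width
  ax <- cfg$osteocyte_axes_range
  margin <- ax[2] + 6
  soma <- list()
  soma_mask <- matrix(FALSE, H, W)

  if (cfg$n_osteocytes > 0L && (W - 2 * margin < 1 || H - 2 * margin < 1))
    stop("scene capacity exceeded: image too small for the requested somas")

  for (k in seq_len(cfg$n_osteocytes)) {
    placed <- FALSE
    for (try in seq_len(1000L)) {
      cx <- stats::runif(1, margin, W - margin)
      cy <- stats::runif(1, margin, H - margin)
      a <- stats::runif(1, ax[1], ax[2])
      b <- stats::runif(1, ax[1], ax[2])
      theta <- stats::runif(1, 0, pi)
      ok <- TRUE
      for (s in soma) {
        lim <- max(a, b) + max(s$a, s$b) + 8
        if ((cx - s$cx)^2 + (cy - s$cy)^2 < lim^2) { ok <- FALSE; break }
      }
      if (ok) {
        px <- ellipse_pixels(cy, cx, a, b, theta, H, W)
        soma[[k]] <- list(id = k, cx = cx, cy = cy, a = a, b = b,
                          theta = theta, pixels = px)
        soma_mask[px] <- TRUE
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop("scene capacity exceeded: could not place soma ", k,
           " after 1000 rejection-sampling retries")
  }

  n <- length(soma)
  dend_mask <- matrix(FALSE, H, W)
  dend_occupied <- integer(0)   # linear indices of committed dendrite pixels
  comp_rows <- list()
  edge_rows <- list()
  de_rows <- list()
  paths <- list()
  comp_id <- 0L

  soma_lin <- lapply(soma, function(s) (s$pixels[, 2L] - 1L) * H + s$pixels[, 1L])
  all_soma_lin <- unlist(soma_lin)

  # Attempt to render one dendritic piece; returns TRUE and commits it when
  # it stays clear (2 px margin) of existing dendrites and (3 px margin) of
  # somas other than `endpoints`.
  try_piece <- function(pl, width, endpoints) {
    ij <- stroke_pixels(pl, width, H, W)
    if (nrow(ij) == 0L) return(NULL)
    lin <- (ij[, 2L] - 1L) * H + ij[, 1L]
    own <- unlist(soma_lin[endpoints])
    outside <- setdiff(lin, own)
    if (length(outside) == 0L) return(NULL)
    zone_d <- grow_pixel_set(ij, 2L, H, W)
    if (length(intersect(zone_d, dend_occupied)) > 0L) return(NULL)
    zone_s <- grow_pixel_set(ij, 3L, H, W)
    other_soma <- setdiff(all_soma_lin, own)
    if (length(intersect(zone_s, other_soma)) > 0L) return(NULL)
    list(lin = lin, outside = outside)
  }

  # planted edges -----------------------------------------------------------
  if (n >= 2L && cfg$connection_probability > 0) {
    pairs <- utils::combn(n, 2L)
    for (q in seq_len(ncol(pairs))) {
      i <- pairs[1L, q]; j <- pairs[2L, q]
      si <- soma[[i]]; sj <- soma[[j]]
      d <- sqrt((si$cx - sj$cx)^2 + (si$cy - sj$cy)^2)
      if (d > cfg$connection_radius) next
      if (stats::runif(1) > cfg$connection_probability) next
      u <- c(sj$cx - si$cx, sj$cy - si$cy) / d
      phi <- atan2(u[2], u[1])
      ri <- ellipse_radius(si$a, si$b, si$theta, phi)
      rj <- ellipse_radius(sj$a, sj$b, sj$theta, phi + pi)
      p0 <- c(si$cx, si$cy) + (ri - 1) * u
      p1 <- c(sj$cx, sj$cy) - (rj - 1) * u
      chord <- sqrt(sum((p1 - p0)^2))
      if (chord < 3) next
      amp <- cfg$dendrite_waviness * chord * stats::runif(1, -1, 1)
      mid <- (p0 + p1) / 2 + amp * c(-u[2], u[1])
      width <- stats::runif(1, cfg$dendrite_width_range[1], cfg$dendrite_width_range[2])
      pl <- bezier_polyline(p0, mid, p1)
      piece <- try_piece(pl, width, c(i, j))
      if (is.null(piece)) next
      comp_id <- comp_id + 1L
      dend_occupied <- c(dend_occupied, piece$lin)
      dend_mask[piece$lin] <- TRUE
      len_px <- free_arc_length(pl, soma[c(i, j)])
      comp_rows[[comp_id]] <- data.frame(
        component = comp_id, area_px = length(piece$outside),
        length_px = len_px, length_um = len_px * cfg$um_per_px,
        thickness_um = width * cfg$um_per_px, n_overlap = 2L,
        role = "edge", stringsAsFactors = FALSE)
      edge_rows[[length(edge_rows) + 1L]] <- data.frame(
        node_a = i, node_b = j, component = comp_id,
        length_um = len_px * cfg$um_per_px,
        thickness_um = width * cfg$um_per_px, stringsAsFactors = FALSE)
      paths[[comp_id]] <- pl
    }
  }

  # dead-end stubs ----------------------------------------------------------
  if (n >= 1L && cfg$dead_end_rate > 0) {
    for (i in seq_len(n)) {
      si <- soma[[i]]
      n_stub <- stats::rpois(1, cfg$dead_end_rate)
      for (s in seq_len(n_stub)) {
        done <- FALSE
        for (try in seq_len(20L)) {
          phi <- stats::runif(1, 0, 2 * pi)
          ri <- ellipse_radius(si$a, si$b, si$theta, phi)
          u <- c(cos(phi), sin(phi))
          L <- stats::runif(1, cfg$dead_end_length_range[1], cfg$dead_end_length_range[2])
          p0 <- c(si$cx, si$cy) + (ri - 1) * u
          p1 <- p0 + L * u
          amp <- cfg$dendrite_waviness * L * stats::runif(1, -1, 1)
          mid <- (p0 + p1) / 2 + amp * c(-u[2], u[1])
          width <- stats::runif(1, cfg$dendrite_width_range[1], cfg$dendrite_width_range[2])
          pl <- bezier_polyline(p0, mid, p1)
          piece <- try_piece(pl, width, i)
          if (is.null(piece)) next
          comp_id <- comp_id + 1L
          dend_occupied <- c(dend_occupied, piece$lin)
          dend_mask[piece$lin] <- TRUE
          len_px <- free_arc_length(pl, soma[i])
          comp_rows[[comp_id]] <- data.frame(
            component = comp_id, area_px = length(piece$outside),
            length_px = len_px, length_um = len_px * cfg$um_per_px,
            thickness_um = width * cfg$um_per_px, n_overlap = 1L,
            role = "dead_end", stringsAsFactors = FALSE)
          de_rows[[length(de_rows) + 1L]] <- data.frame(
            node = i, component = comp_id,
            length_um = len_px * cfg$um_per_px, stringsAsFactors = FALSE)
          paths[[comp_id]] <- pl
          done <- TRUE
          break
        }
        # stub skipped when no clear direction was found; the planted graph
        # only records rendered structures
      }
    }
  }

  nodes <- if (n > 0L) {
    data.frame(id = seq_len(n),
               x = vapply(soma, `[[`, numeric(1), "cx"),
               y = vapply(soma, `[[`, numeric(1), "cy"),
               area_px = vapply(soma_lin, length, integer(1)))
  } else {
    data.frame(id = integer(0), x = numeric(0), y = numeric(0), area_px = integer(0))
  }
  graph <- new_lcn_graph(
    nodes = nodes,
    edges = rbind_or_empty(edge_rows, c("node_a", "node_b", "component", "length_um", "thickness_um")),
    dead_ends = rbind_or_empty(de_rows, c("node", "component", "length_um")),
    isolated = data.frame(component = integer(0)),
    components = rbind_or_empty(comp_rows, c("component", "area_px", "length_px",
                                             "length_um", "thickness_um", "n_overlap", "role")),
    um_per_px = cfg$um_per_px)
  graph$paths <- paths

  scene <- list(image = NULL, mask = NULL, graph = graph, config = cfg)
  class(scene) <- "lcn_scene"
  if (!render) return(scene)

  mask <- matrix(0L, H, W)
  mask[dend_mask] <- 2L
  mask[soma_mask] <- 1L
  img <- matrix(cfg$background_intensity, H, W)
  img[mask == 2L] <- cfg$dendrite_intensity
  img[mask == 1L] <- cfg$soma_intensity
  img <- apply_noise(img, cfg$noise_sd, cfg$illumination_gradient, seed = NULL)
  scene$image <- img
  scene$mask <- mask
  scene
}

# Arc length of the part of a polyline lying outside the given somas
# (the canalicular span between soma boundaries).
free_arc_length <- function(pl, somas) {
  inside <- rep(FALSE, nrow(pl))
  for (s in somas) {
    dx <- pl[, 1] - s$cx; dy <- pl[, 2] - s$cy
    xr <- dx * cos(s$theta) + dy * sin(s$theta)
    yr <- -dx * sin(s$theta) + dy * cos(s$theta)
    inside <- inside | (xr / s$a)^2 + (yr / s$b)^2 <= 1
  }
  seg <- sqrt(diff(pl[, 1])^2 + diff(pl[, 2])^2)
  keep <- !(inside[-1L] | inside[-nrow(pl)])
  sum(seg[keep])
}

rbind_or_empty <- function(rows, cols) {
  if (length(rows) > 0L) return(do.call(rbind, rows))
  out <- as.data.frame(stats::setNames(replicate(length(cols), numeric(0), simplify = FALSE), cols))
  out
}

#' @export
print.lcn_scene <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<lcn_scene> %dx%d px, %d somas, %d connections, %d dead ends\n",
              cfg$image_height, cfg$image_width, nrow(x$graph$nodes),
              nrow(x$graph$edges), nrow(x$graph$dead_ends)))
  invisible(x)
}
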