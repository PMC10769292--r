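# Independent brute-force oracles used to pin expected values.

# Direct 2D convolution with a truncated Gaussian and reflecting borders.
brute_gaussian_2d <- function(image, sigma) {
  r <- ceiling(4 * sigma)
  k1 <- exp(-((-r):r)^2 / (2 * sigma^2)); k1 <- k1 / sum(k1)
  K <- outer(k1, k1)
  H <- nrow(image); W <- ncol(image)
  refl <- function(j, n) ifelse(j < 1L, 1L - j, ifelse(j > n, 2L * n + 1L - j, j))
  out <- matrix(0, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    acc <- 0
    for (di in -r:r) for (dj in -r:r) {
      acc <- acc + K[di + r + 1L, dj + r + 1L] *
        image[refl(i + di, H), refl(j + dj, W)]
    }
    out[i, j] <- acc
  }
  out
}

# Exhaustive 256-way Otsu: smallest t in (lo, hi] maximising between-class
# variance of [lo, t-1] vs [t, hi].
brute_otsu <- function(image, lo, hi) {
  v <- round(image)
  v <- v[v >= lo & v <= hi]
  best_t <- NA_integer_; best_sb <- -Inf
  for (t in (lo + 1L):hi) {
    a <- v[v < t]; b <- v[v >= t]
    if (length(a) == 0L || length(b) == 0L) next
    w0 <- length(a) / length(v); w1 <- 1 - w0
    sb <- w0 * w1 * (mean(a) - mean(b))^2
    if (sb > best_sb + 1e-12) { best_sb <- sb; best_t <- t }
  }
  best_t
}

# Queue-based flood fill, raster-order (row-major) component numbering.
brute_flood_fill <- function(mask, connectivity) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  offs <- if (connectivity == 4) list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
          else list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1),
                    c(0, 1), c(1, -1), c(1, 0), c(1, 1))
  nxt <- 0L
  for (i0 in seq_len(H)) for (j0 in seq_len(W)) {
    if (!mask[i0, j0] || lab[i0, j0] > 0L) next
    nxt <- nxt + 1L
    queue <- list(c(i0, j0)); lab[i0, j0] <- nxt
    while (length(queue) > 0L) {
      p <- queue[[1L]]; queue <- queue[-1L]
      for (o in offs) {
        qi <- p[1L] + o[1L]; qj <- p[2L] + o[2L]
        if (qi >= 1L && qi <= H && qj >= 1L && qj <= W &&
            mask[qi, qj] && lab[qi, qj] == 0L) {
          lab[qi, qj] <- nxt
          queue[[length(queue) + 1L]] <- c(qi, qj)
        }
      }
    }
  }
  lab
}

# Per-component penalty by explicit loop over a labelled component map.
brute_penalty <- function(bin, penalty_factor, weight) {
  lab <- brute_flood_fill(bin, 8)
  n <- max(lab)
  if (n == 0L) return(0)
  total <- 0
  for (k in seq_len(n)) total <- total + sum(lab == k)^(-penalty_factor)
  total * weight
}

# One-hot logits (scaled) realising a given label map.
logits_from_label <- function(label, n_classes = 3L, scale = 10) {
  z <- array(0, c(nrow(label), ncol(label), n_classes))
  for (k in 0:(n_classes - 1L)) z[, , k + 1L][label == k] <- scale
  z
}

# All-pairs hop counts by Floyd-Warshall on an edge list.
brute_mean_shortest_path <- function(n, edges_a, edges_b) {
  if (n == 0L || length(edges_a) == 0L) return(NA_real_)
  D <- matrix(Inf, n, n); diag(D) <- 0
  for (k in seq_along(edges_a)) {
    D[edges_a[k], edges_b[k]] <- 1
    D[edges_b[k], edges_a[k]] <- 1
  }
  for (m in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (D[i, m] + D[m, j] < D[i, j]) D[i, j] <- D[i, m] + D[m, j]
  }
  d <- D[upper.tri(D)]
  d <- d[is.finite(d) & d > 0]
  if (length(d) == 0L) return(NA_real_)
  mean(d)
}
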