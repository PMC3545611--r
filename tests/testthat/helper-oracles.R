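# Independent brute-force oracles, deliberately naive: each re-derives a
# result by direct definition so the vectorized implementation is checked
# against something that shares none of its code path.

# Point-to-segment distance by dense sampling of the segment.
oracle_segment_distance <- function(p, p0, p1, n = 20001L) {
  t <- seq(0, 1, length.out = n)
  pts <- outer(t, p1 - p0) + rep(p0, each = n)
  min(sqrt(rowSums((pts - rep(p, each = n))^2)))
}

# Per-pixel double-loop segmentation through a logical bin vector.
oracle_segment_image <- function(codes, bins) {
  out <- matrix(FALSE, nrow(codes), ncol(codes))
  for (i in seq_len(nrow(codes)))
    for (j in seq_len(ncol(codes)))
      out[i, j] <- bins[codes[i, j] + 1L]
  out
}

# Per-pixel threshold-rule evaluation on decoded channel bins.
oracle_threshold_segment <- function(codes, rule) {
  out <- matrix(FALSE, nrow(codes), ncol(codes))
  for (i in seq_len(nrow(codes))) {
    for (j in seq_len(ncol(codes))) {
      ch <- decode_rgb565(codes[i, j])
      ok <- TRUE
      for (cn in c("r", "g", "b")) {
        v <- ch[1L, c(r = 1L, g = 2L, b = 3L)[[cn]]]
        lo <- rule[[paste0(cn, "_gt")]]; hi <- rule[[paste0(cn, "_lt")]]
        if (!is.null(lo) && !(v > lo)) ok <- FALSE
        if (!is.null(hi) && !(v < hi)) ok <- FALSE
      }
      out[i, j] <- ok
    }
  }
  out
}

# Largest connected component by queue-based flood fill.
oracle_largest_component <- function(mask, connectivity = 8L) {
  h <- nrow(mask); w <- ncol(mask)
  labels <- matrix(0L, h, w)
  nb <- if (connectivity == 4L) {
    cbind(c(-1L, 1L, 0L, 0L), c(0L, 0L, -1L, 1L))
  } else {
    as.matrix(expand.grid(dr = -1:1, dc = -1:1))[-5L, ]
  }
  lab <- 0L
  comp_pixels <- list()
  # scan in row-major order so component ids follow the tie-break rule
  for (i in seq_len(h)) for (j in seq_len(w)) {
    if (!mask[i, j] || labels[i, j] > 0L) next
    lab <- lab + 1L
    queue <- list(c(i, j)); labels[i, j] <- lab
    px <- list()
    while (length(queue)) {
      p <- queue[[1L]]; queue <- queue[-1L]
      px[[length(px) + 1L]] <- p
      for (k in seq_len(nrow(nb))) {
        ni <- p[1L] + nb[k, 1L]; nj <- p[2L] + nb[k, 2L]
        if (ni >= 1L && ni <= h && nj >= 1L && nj <= w &&
            mask[ni, nj] && labels[ni, nj] == 0L) {
          labels[ni, nj] <- lab
          queue[[length(queue) + 1L]] <- c(ni, nj)
        }
      }
    }
    comp_pixels[[lab]] <- px
  }
  if (lab == 0L) return(mask)
  sizes <- lengths(comp_pixels)
  best <- which(sizes == max(sizes))[1L]  # earliest row-major seed wins ties
  out <- matrix(FALSE, h, w)
  for (p in comp_pixels[[best]]) out[p[1L], p[2L]] <- TRUE
  out
}

random_codes <- function(h, w) {
  matrix(sample(0:65535, h * w, replace = TRUE), h, w)
}

random_lut <- function(p = 0.5, layout = "bitpacked") {
  segmentation_lut(runif(65536) < p, layout = layout)
}

# A tiny scene configuration for fast tests.
tiny_scene <- function(seed, ...) {
  generate_scene(scene_params(n_fruit = 2L, fruit_radius = c(24, 40),
                              seed = seed, ...))
}
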