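# Independent oracles used across the suite. These never call the code paths
# they check.

# Thompson-Larson-Webb localization precision (nm): PSF sigma s, photon count
# N, pixel size a, background noise sd b (photons per pixel).
thompson_precision_nm <- function(s_nm, N, a_nm, b) {
  sqrt(s_nm^2 / N + a_nm^2 / (12 * N) + 8 * pi * s_nm^4 * b^2 / (a_nm^2 * N^2))
}

# brute-force O(n^2) pair-distance bin counts, half-open bins on [0, r_max)
brute_pair_counts <- function(xy, r_max, bin_width) {
  d <- as.vector(stats::dist(xy))
  d <- d[d < r_max]
  tabulate(floor(d / bin_width) + 1L, nbins = ceiling(r_max / bin_width))
}

brute_cross_counts <- function(xya, xyb, r_max, bin_width) {
  d <- sqrt(outer(xya[, 1], xyb[, 1], "-")^2 + outer(xya[, 2], xyb[, 2], "-")^2)
  d <- d[d < r_max]
  tabulate(floor(d / bin_width) + 1L, nbins = ceiling(r_max / bin_width))
}

brute_coloc_pct <- function(xya, xyb, radius) {
  d <- sqrt(outer(xya[, 1], xyb[, 1], "-")^2 + outer(xya[, 2], xyb[, 2], "-")^2)
  c(pct_A = 100 * mean(apply(d, 1, min) <= radius),
    pct_B = 100 * mean(apply(d, 2, min) <= radius))
}

# sampled (pixel-centre) 2D Gaussian frame: the exact model fit_gaussian_2d
# assumes, for render-and-refit identities
sampled_gaussian_frame <- function(nr, nc, x0_px, y0_px, amplitude, sigma_px,
                                   offset = 0) {
  X <- matrix(seq_len(nc) - 0.5, nr, nc, byrow = TRUE)
  Y <- matrix(seq_len(nr) - 0.5, nr, nc)
  offset + amplitude * exp(-((X - x0_px)^2 + (Y - y0_px)^2) / (2 * sigma_px^2))
}

# straight single-belt geometry of known length (um) for count oracles
straight_belt_geometry <- function(length_um = 100, width_um = 10) {
  junction_geometry(
    list(matrix(c(0, width_um * 500, length_um * 1000, width_um * 500),
                2, 2, byrow = TRUE)),
    c(length_um * 1000, width_um * 1000), n_cells = 2L)
}

# smooth textured source image for stitching tests
textured_image <- function(nr, nc, seed = 1) {
  set.seed(seed)
  round(gauss_blur_for_tests(matrix(runif(nr * nc, 0, 4000), nr, nc), 2))
}

# brute-force 2D convolution oracle, independent of the package's blur
gauss_blur_for_tests <- function(m, sigma) {
  r <- ceiling(3 * sigma)
  k <- outer(dnorm(-r:r, 0, sigma), dnorm(-r:r, 0, sigma))
  k <- k / sum(k)
  nr <- nrow(m); nc <- ncol(m)
  pad <- matrix(0, nr + 2 * r, nc + 2 * r)
  pad[r + seq_len(nr), r + seq_len(nc)] <- m
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc))
    out[i, j] <- sum(pad[i:(i + 2 * r), j:(j + 2 * r)] * k)
  out
}

# cut a 2x2 tile grid out of a source image, optionally with per-tile jitter;
# a margin keeps jittered tiles inside the source
cut_tiles <- function(src, tile, step, jitter = NULL) {
  margin <- if (is.null(jitter)) 0L else 5L
  lapply(1:2, function(i) lapply(1:2, function(j) {
    r0 <- margin + (i - 1) * step; c0 <- margin + (j - 1) * step
    if (!is.null(jitter)) {
      r0 <- r0 + jitter[[i]][[j]][1]; c0 <- c0 + jitter[[i]][[j]][2]
    }
    src[r0 + seq_len(tile), c0 + seq_len(tile)]
  }))
}

# minimum distance from each point to any belt segment of a geometry
min_dist_to_belts <- function(geometry, xy) {
  segs <- do.call(rbind, lapply(geometry$belts, function(b) {
    cbind(b[-nrow(b), , drop = FALSE], b[-1, , drop = FALSE])
  }))
  apply(xy, 1, function(p) {
    min(apply(segs, 1, function(s) {
      v <- s[3:4] - s[1:2]
      t0 <- sum((p - s[1:2]) * v) / sum(v^2)
      t0 <- min(max(t0, 0), 1)
      sqrt(sum((p - s[1:2] - t0 * v)^2))
    }))
  })
}
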