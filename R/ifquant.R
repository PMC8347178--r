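#' Maximum-intensity projection of a z-stack
#'
#' @param stack an [image_stack()] (or a bare `rows x cols x slices` array).
#' @return Matrix of the per-pixel maximum over slices.
#' @export
max_project <- function(stack) {
  data <- if (inherits(stack, "image_stack")) stack$data else stack
  if (is.matrix(data)) data <- array(data, c(dim(data), 1L))
  if (length(dim(data)) != 3 || dim(data)[3] < 1) stop("empty stack")
  out <- data[, , 1]
  for (k in seq_len(dim(data)[3])[-1]) out <- pmax(out, data[, , k])
  out
}

# normalized cross-correlation of the overlap between ref (at origin) and
# tile placed at integer offset (orow, ocol) relative to ref; NA if degenerate
overlap_ncc <- function(ref, tile, orow, ocol) {
  h <- nrow(ref); w <- ncol(ref)
  r_lo <- max(1L, orow + 1L); r_hi <- min(h, orow + nrow(tile))
  c_lo <- max(1L, ocol + 1L); c_hi <- min(w, ocol + ncol(tile))
  if (r_hi - r_lo < 1L || c_hi - c_lo < 1L) return(NA_real_)
  r1 <- r_lo:r_hi; c1 <- c_lo:c_hi
  a <- as.vector(ref[r1, c1])
  b <- as.vector(tile[r1 - orow, c1 - ocol])
  if (sd(a) == 0 || sd(b) == 0) return(NA_real_)
  suppressWarnings(stats::cor(a, b))
}

# refine the offset of `tile` relative to `ref` around a nominal integer
# offset, searching +/- search_px; returns c(orow, ocol) and the NCC score
refine_offset <- function(ref, tile, nominal, search_px) {
  best <- c(nominal, NA_real_)
  for (dr in -search_px:search_px) {
    for (dc in -search_px:search_px) {
      s <- overlap_ncc(ref, tile, nominal[1] + dr, nominal[2] + dc)
      if (!is.na(s) && (is.na(best[3]) || s > best[3]))
        best <- c(nominal[1] + dr, nominal[2] + dc, s)
    }
  }
  best
}

#' Stitch a grid of overlapping image tiles into a mosaic
#'
#' Tiles are assumed to lie on a regular grid with a nominal fractional
#' overlap (the whole-filter surveys here use 10%). Pairwise translations are
#' refined from the nominal grid offsets by integer-pixel normalized
#' cross-correlation within a small search window, then overlapping pixels are
#' blended by linear feathering. Featureless overlaps fall back to the
#' nominal offsets with a warning.
#'
#' @param tiles list of rows, each a list of equally sized matrices
#'   (`tiles[[i]][[j]]` is the tile in grid row `i`, column `j`).
#' @param nominal_overlap nominal fractional overlap in `[0, 0.5)`.
#' @param search_px half-width of the integer offset search window.
#' @return The mosaic matrix; attribute `offsets` is an `n x 4` matrix
#'   (`grid_row`, `grid_col`, `row_px`, `col_px`) of refined absolute
#'   top-left tile positions (0-based).
#' @export
stitch_tiles <- function(tiles, nominal_overlap = 0.1, search_px = 5L) {
  stopifnot(nominal_overlap >= 0, nominal_overlap < 0.5)
  nr_g <- length(tiles); nc_g <- length(tiles[[1]])
  for (row in tiles) stopifnot(length(row) == nc_g)
  h <- nrow(tiles[[1]][[1]]); w <- ncol(tiles[[1]][[1]])
  if (nr_g == 1L && nc_g == 1L) {
    out <- tiles[[1]][[1]]
    attr(out, "offsets") <- cbind(grid_row = 1, grid_col = 1, row_px = 0, col_px = 0)
    return(out)
  }
  step_r <- round(h * (1 - nominal_overlap))
  step_c <- round(w * (1 - nominal_overlap))

  pos <- array(NA_real_, c(nr_g, nc_g, 2))
  pos[1, 1, ] <- c(0, 0)
  fell_back <- FALSE
  for (i in seq_len(nr_g)) {
    for (j in seq_len(nc_g)) {
      if (i == 1L && j == 1L) next
      if (j > 1L) {
        ref <- tiles[[i]][[j - 1L]]; ref_pos <- pos[i, j - 1L, ]
        nominal <- c(0L, step_c)
      } else {
        ref <- tiles[[i - 1L]][[j]]; ref_pos <- pos[i - 1L, j, ]
        nominal <- c(step_r, 0L)
      }
      best <- refine_offset(ref, tiles[[i]][[j]], nominal, search_px)
      if (is.na(best[3])) { best[1:2] <- nominal; fell_back <- TRUE }
      pos[i, j, ] <- ref_pos + best[1:2]
    }
  }
  if (fell_back)
    warning("featureless overlap: fell back to nominal offsets for some tiles")

  pos[, , 1] <- pos[, , 1] - min(pos[, , 1])
  pos[, , 2] <- pos[, , 2] - min(pos[, , 2])
  H <- max(pos[, , 1]) + h; W <- max(pos[, , 2]) + w
  acc <- matrix(0, H, W); wt <- matrix(0, H, W)
  feather <- outer(pmin(seq_len(h), rev(seq_len(h))),
                   pmin(seq_len(w), rev(seq_len(w))))
  offsets <- matrix(0, nr_g * nc_g, 4,
                    dimnames = list(NULL, c("grid_row", "grid_col", "row_px", "col_px")))
  k <- 0L
  for (i in seq_len(nr_g)) {
    for (j in seq_len(nc_g)) {
      r0 <- pos[i, j, 1]; c0 <- pos[i, j, 2]
      rows <- (r0 + 1):(r0 + h); cols <- (c0 + 1):(c0 + w)
      acc[rows, cols] <- acc[rows, cols] + tiles[[i]][[j]] * feather
      wt[rows, cols] <- wt[rows, cols] + feather
      k <- k + 1L
      offsets[k, ] <- c(i, j, r0, c0)
    }
  }
  out <- acc / pmax(wt, .Machine$double.eps)
  attr(out, "offsets") <- offsets
  out
}

#' Intensity per analyzed area inside an ROI
#'
#' Sum of grey values inside the ROI divided by the ROI pixel count
#' (intensity / analyzed area, in arbitrary units per pixel). Whole-image
#' quantification uses a full-true mask.
#'
#' @param image 2D matrix (e.g. a maximum projection).
#' @param roi an [roi_mask()] congruent with `image`, or `NULL` for the whole
#'   image.
#' @return Mean intensity over the ROI (A.U.).
#' @export
quantify_intensity <- function(image, roi = NULL) {
  if (is.null(roi)) return(sum(image) / length(image))
  stopifnot(inherits(roi, "roi_mask"), all(dim(roi$mask) == dim(image)))
  n <- sum(roi$mask)
  if (n == 0L) stop("empty ROI")
  sum(image[roi$mask]) / n
}

#' Sample random junction-area ROI patches
#'
#' Emulates the manual selection of random junction areas: `n` square patches
#' are centred on uniformly sampled junction (true-mask) pixels, constrained
#' to be pairwise disjoint, and each patch is intersected with the junction
#' mask.
#'
#' @param mask an [roi_mask()] of the junction belt.
#' @param n number of patches.
#' @param patch_nm patch edge length in nm.
#' @param seed integer RNG seed.
#' @return List of `n` [roi_mask()]s congruent with `mask`. Errors when `n`
#'   disjoint patches cannot be placed, reporting the feasible number.
#' @export
sample_junction_rois <- function(mask, n, patch_nm, seed = 1L) {
  stopifnot(inherits(mask, "roi_mask"), n >= 1)
  set.seed(seed)
  half <- max(0L, round(patch_nm / mask$pixel_nm / 2))
  cand <- which(mask$mask, arr.ind = TRUE)
  if (nrow(cand) == 0L) stop("mask has no junction pixels")
  cand <- cand[sample.int(nrow(cand)), , drop = FALSE]
  occupied <- matrix(FALSE, nrow(mask$mask), ncol(mask$mask))
  out <- list()
  for (k in seq_len(nrow(cand))) {
    r <- cand[k, 1]; c <- cand[k, 2]
    rows <- max(1L, r - half):min(nrow(occupied), r + half)
    cols <- max(1L, c - half):min(ncol(occupied), c + half)
    if (any(occupied[rows, cols])) next
    occupied[rows, cols] <- TRUE
    patch <- matrix(FALSE, nrow(occupied), ncol(occupied))
    patch[rows, cols] <- TRUE
    out[[length(out) + 1L]] <- roi_mask(patch & mask$mask, mask$pixel_nm)
    if (length(out) == n) break
  }
  if (length(out) < n)
    stop(sprintf("cannot place %d disjoint patches; at most %d feasible",
                 n, length(out)))
  out
}
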