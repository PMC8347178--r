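as_xy <- function(points) {
  if (is.matrix(points)) {
    stopifnot(ncol(points) == 2)
    return(points)
  }
  if (is.data.frame(points)) {
    stopifnot(all(c("x_nm", "y_nm") %in% names(points)))
    return(cbind(points$x_nm, points$y_nm))
  }
  stop("points must be a 2-column matrix or a data.frame with x_nm/y_nm")
}

new_distance_histogram <- function(counts, r_max, bin_width) {
  n_pairs <- sum(counts)
  structure(list(
    bin_edges_nm = seq(0, by = bin_width, length.out = length(counts) + 1L),
    rel_freq = if (n_pairs > 0) counts / n_pairs else counts,
    counts = counts, n_pairs = n_pairs, r_max = r_max,
    bin_width = bin_width), class = "distance_histogram")
}

#' @export
print.distance_histogram <- function(x, ...) {
  cat(sprintf("distance_histogram: %d bins of %.0f nm on [0, %.0f), %d pairs\n",
              length(x$rel_freq), x$bin_width, x$r_max, x$n_pairs))
  invisible(x)
}

#' Relative pairwise-distance distribution histogram
#'
#' The clustering readout: all unordered point pairs closer than `r_max` are
#' binned on half-open bins `[0, r_max)` and normalized by the number of
#' pairs counted, giving a relative frequency spectrum. Short-distance excess
#' over a complete-spatial-randomness reference indicates molecular
#' clustering. Neighbour search uses a cell-list spatial index, exact and
#' identical to all-pairs enumeration.
#'
#' @param points a [loc_table()], a data.frame with `x_nm`/`y_nm`, or a
#'   2-column matrix of nm coordinates (>= 2 points).
#' @param r_max maximum distance (nm); 200 for same-channel spectra, 400 for
#'   cross-channel.
#' @param bin_width bin width (nm).
#' @return A `distance_histogram` with `bin_edges_nm`, `rel_freq` (sums to 1
#'   when any pair is counted), `counts`, `n_pairs` and `r_max`.
#' @export
pairwise_distance_histogram <- function(points, r_max = 200, bin_width = 10) {
  xy <- as_xy(points)
  if (nrow(xy) < 2L) stop("need at least 2 points")
  stopifnot(r_max > 0, bin_width > 0)
  counts <- .pair_hist_counts(xy[, 1], xy[, 2], r_max, bin_width)
  new_distance_histogram(counts, r_max, bin_width)
}

#' Cross-channel pairwise-distance histogram
#'
#' As [pairwise_distance_histogram()], but over all ordered A-B pairs of two
#' channels (e.g. ZO-1 vs claudin-5), by default up to 400 nm.
#'
#' @param points_A,points_B point sets (see [pairwise_distance_histogram()]);
#'   both nonempty.
#' @param r_max maximum distance (nm).
#' @param bin_width bin width (nm).
#' @return A `distance_histogram`.
#' @export
cross_pairwise_histogram <- function(points_A, points_B, r_max = 400,
                                     bin_width = 10) {
  xya <- as_xy(points_A); xyb <- as_xy(points_B)
  if (nrow(xya) < 1L || nrow(xyb) < 1L) stop("both channels must be nonempty")
  stopifnot(r_max > 0, bin_width > 0)
  counts <- .cross_hist_counts(xya[, 1], xya[, 2], xyb[, 1], xyb[, 2],
                               r_max, bin_width)
  new_distance_histogram(counts, r_max, bin_width)
}

#' Complete-spatial-randomness reference spectrum
#'
#' Simulates `n_sim` uniform placements of `n_points` inside the ROI mask and
#' summarizes their pairwise-distance spectra: per-bin mean relative
#' frequency and a pointwise 2.5%/97.5% quantile envelope. Conditioning the
#' null on the same mask as the observed data absorbs edge and ROI-shape
#' effects, so no analytic edge correction is applied.
#'
#' @param n_points points per simulation (>= 2).
#' @param roi an [roi_mask()]; uniform points are drawn inside true pixels.
#' @param r_max,bin_width histogram parameters (match the observed spectrum).
#' @param n_sim number of simulations (>= 20).
#' @param seed integer RNG seed.
#' @return A `csr_reference`: `mean`, `lo`, `hi` (per-bin), `bin_edges_nm`,
#'   `n_sim`, `n_points`. The envelope is rank-based (the standard Monte
#'   Carlo construction): `lo`/`hi` are the order statistics nearest the
#'   2.5%/97.5% tails, so a new CSR realization falls inside with
#'   probability about 95-96%.
#' @export
csr_reference <- function(n_points, roi, r_max = 200, bin_width = 10,
                          n_sim = 99L, seed = 1L) {
  stopifnot(n_points >= 2, n_sim >= 20, inherits(roi, "roi_mask"))
  idx <- which(roi$mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("ROI mask is empty")
  if (nrow(idx) * 4 < n_points)
    stop("ROI too small to hold the requested number of points")
  set.seed(seed)
  nbins <- length(.pair_hist_counts(c(0, 1), c(0, 1), r_max, bin_width))
  freqs <- matrix(0, n_sim, nbins)
  p <- roi$pixel_nm
  for (s in seq_len(n_sim)) {
    pick <- idx[sample.int(nrow(idx), n_points, replace = TRUE), , drop = FALSE]
    x <- (pick[, 2] - 1) * p + runif(n_points, 0, p)
    y <- (pick[, 1] - 1) * p + runif(n_points, 0, p)
    counts <- .pair_hist_counts(x, y, r_max, bin_width)
    tot <- sum(counts)
    freqs[s, ] <- if (tot > 0) counts / tot else counts
  }
  r_lo <- max(1L, floor(0.025 * (n_sim + 1L)))
  r_hi <- min(n_sim, ceiling(0.975 * (n_sim + 1L)))
  structure(list(
    mean = colMeans(freqs),
    lo = apply(freqs, 2, function(v) sort(v)[r_lo]),
    hi = apply(freqs, 2, function(v) sort(v)[r_hi]),
    bin_edges_nm = seq(0, by = bin_width, length.out = nbins + 1L),
    bin_width = bin_width, r_max = r_max,
    n_sim = n_sim, n_points = n_points), class = "csr_reference")
}

#' Clustering excess at an evaluation distance
#'
#' Compares the observed relative frequency in the bin containing
#' `r_eval_nm` (default 40 nm, where tightened claudin-5 belts show their
#' clustering signature) with the CSR reference: `excess_ratio =
#' observed / csr_mean`, with a `clustered` flag when the observation exceeds
#' the pointwise upper envelope in that bin.
#'
#' @param obs an observed `distance_histogram`.
#' @param csr a [csr_reference()] with matching bins.
#' @param r_eval_nm evaluation distance (nm).
#' @return A `cluster_metric`: `r_eval_nm`, `observed_freq`, `csr_mean_freq`,
#'   `excess_ratio`, `csr_envelope` (`lo`, `hi`), `clustered`, `flagged`
#'   (TRUE when the CSR mean is zero and the ratio undefined).
#' @export
clustering_excess <- function(obs, csr, r_eval_nm = 40) {
  stopifnot(inherits(obs, "distance_histogram"), inherits(csr, "csr_reference"))
  if (obs$bin_width != csr$bin_width || obs$r_max != csr$r_max)
    stop("observed histogram and CSR reference bins do not match")
  b <- findInterval(r_eval_nm, obs$bin_edges_nm, rightmost.closed = FALSE)
  if (b < 1L || b > length(obs$rel_freq))
    stop("r_eval_nm outside the histogram range")
  o <- obs$rel_freq[b]; m <- csr$mean[b]
  flagged <- m == 0
  if (flagged) warning("CSR mean frequency is zero in the evaluation bin; excess ratio undefined")
  structure(list(
    r_eval_nm = r_eval_nm, observed_freq = o, csr_mean_freq = m,
    excess_ratio = if (flagged) NA_real_ else o / m,
    csr_envelope = c(lo = csr$lo[b], hi = csr$hi[b]),
    clustered = !flagged && o > csr$hi[b],
    flagged = flagged), class = "cluster_metric")
}

#' @export
print.cluster_metric <- function(x, ...) {
  cat(sprintf("cluster_metric at %.0f nm: observed %.4f vs CSR %.4f (ratio %.2f), envelope [%.4f, %.4f] -> %s\n",
              x$r_eval_nm, x$observed_freq, x$csr_mean_freq, x$excess_ratio,
              x$csr_envelope[1], x$csr_envelope[2],
              if (isTRUE(x$clustered)) "clustered" else "not clustered"))
  invisible(x)
}

#' Coordinate-based two-channel colocalization
#'
#' A molecule counts as colocalized when at least one molecule of the other
#' channel lies within `radius_nm` (default 90 nm, the span of two
#' fluorophore-conjugated antibodies at minimal distance); each molecule is
#' counted once regardless of how many partners it has. Percentages are
#' reported for both channels; swapping the channels swaps the two
#' percentages.
#'
#' @param table_A,table_B point sets in the same coordinate frame
#'   ([loc_table()], data.frame with `x_nm`/`y_nm`, or 2-column matrix); both
#'   nonempty.
#' @param radius_nm colocalization radius (nm).
#' @return A `coloc_result`: `radius_nm`, `n_A`, `n_B`, `pct_A_coloc` (% of A
#'   with a B partner within radius), `pct_B_coloc`.
#' @export
colocalize <- function(table_A, table_B, radius_nm = 90) {
  xya <- as_xy(table_A); xyb <- as_xy(table_B)
  if (nrow(xya) < 1L || nrow(xyb) < 1L) stop("both channels must be nonempty")
  stopifnot(radius_nm > 0)
  a_hit <- .has_neighbor_within(xya[, 1], xya[, 2], xyb[, 1], xyb[, 2], radius_nm)
  b_hit <- .has_neighbor_within(xyb[, 1], xyb[, 2], xya[, 1], xya[, 2], radius_nm)
  structure(list(radius_nm = radius_nm, n_A = nrow(xya), n_B = nrow(xyb),
                 pct_A_coloc = 100 * mean(a_hit),
                 pct_B_coloc = 100 * mean(b_hit)),
            class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf("coloc_result (radius %.0f nm): %.1f%% of %d A-molecules, %.1f%% of %d B-molecules\n",
              x$radius_nm, x$pct_A_coloc, x$n_A, x$pct_B_coloc, x$n_B))
  invisible(x)
}

#' Write a distance histogram (with optional CSR reference) to CSV
#'
#' @param obs a `distance_histogram`.
#' @param path output CSV path.
#' @param csr optional matching [csr_reference()].
#' @return `path`, invisibly. Columns: `bin_lo`, `bin_hi`, `rel_freq` and,
#'   when a reference is given, `csr_mean`, `csr_lo`, `csr_hi`.
#' @export
write_histogram_csv <- function(obs, path, csr = NULL) {
  df <- data.frame(bin_lo = obs$bin_edges_nm[-length(obs$bin_edges_nm)],
                   bin_hi = obs$bin_edges_nm[-1], rel_freq = obs$rel_freq)
  if (!is.null(csr)) {
    df$csr_mean <- csr$mean; df$csr_lo <- csr$lo; df$csr_hi <- csr$hi
  }
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
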