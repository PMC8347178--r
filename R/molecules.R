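# sample n points uniformly along the belt arc length
sample_on_belts <- function(geometry, n) {
  if (n == 0L)
    return(matrix(numeric(0), 0, 2))
  segs <- do.call(rbind, lapply(geometry$belts, function(b) {
    cbind(b[-nrow(b), , drop = FALSE], b[-1, , drop = FALSE])
  }))
  len <- sqrt((segs[, 3] - segs[, 1])^2 + (segs[, 4] - segs[, 2])^2)
  cum <- cumsum(len)
  u <- runif(n, 0, cum[length(cum)])
  idx <- findInterval(u, cum, left.open = TRUE) + 1L
  t0 <- (u - c(0, cum)[idx]) / len[idx]
  cbind(segs[idx, 1] + t0 * (segs[idx, 3] - segs[idx, 1]),
        segs[idx, 2] + t0 * (segs[idx, 4] - segs[idx, 2]))
}

clamp_to_field <- function(xy, field) {
  xy[, 1] <- pmin(pmax(xy[, 1], 0), field[1])
  xy[, 2] <- pmin(pmax(xy[, 2], 0), field[2])
  xy
}

#' Place fluorophores on a junction geometry
#'
#' Ground-truth molecule placement for the simulator. The expected total
#' molecule count is `belt_length_um * linear_density_per_um` in both modes
#' (the realized count is Poisson). In dispersed mode molecules fall uniformly
#' along the belt arc length; in clustered mode cluster parents fall uniformly
#' along the belt and offspring are scattered isotropically with
#' `cluster_sigma_nm`. A fraction `off_belt_fraction` is placed uniformly over
#' the field to emulate non-junctional background labelling.
#'
#' @param geometry a [junction_geometry()].
#' @param params a [clustering_params()].
#' @param seed integer RNG seed.
#' @return A data.frame of class `ground_truth_molecules` with columns `x_nm`,
#'   `y_nm`, `cluster_id` (`-1` for non-clustered molecules) and attributes
#'   `field_size_nm` and `params`.
#' @export
place_fluorophores <- function(geometry, params, seed = 1L) {
  stopifnot(inherits(geometry, "junction_geometry"),
            inherits(params, "clustering_params"))
  set.seed(seed)
  field <- geometry$field_size_nm
  lambda <- belt_length(geometry, "um") * params$linear_density_per_um
  n_total <- rpois(1L, lambda)

  n_off <- rbinom(1L, n_total, params$off_belt_fraction)
  n_on <- n_total - n_off

  if (params$mode == "dispersed") {
    xy_on <- sample_on_belts(geometry, n_on)
    id_on <- rep(-1L, n_on)
  } else {
    mu <- params$mean_molecules_per_cluster
    n_par <- rpois(1L, n_on / mu)
    if (n_par > 0L) {
      parents <- sample_on_belts(geometry, n_par)
      kids <- rpois(n_par, mu)
      id_on <- rep(seq_len(n_par), kids)
      xy_on <- parents[id_on, , drop = FALSE] +
        matrix(rnorm(2L * sum(kids), 0, params$cluster_sigma_nm), ncol = 2)
      xy_on <- clamp_to_field(xy_on, field)
    } else {
      xy_on <- matrix(numeric(0), 0, 2)
      id_on <- integer(0)
    }
  }
  xy_off <- cbind(runif(n_off, 0, field[1]), runif(n_off, 0, field[2]))
  xy <- rbind(xy_on, xy_off)
  out <- data.frame(x_nm = xy[, 1], y_nm = xy[, 2],
                    cluster_id = c(id_on, rep(-1L, n_off)))
  structure(out, class = c("ground_truth_molecules", "data.frame"),
            field_size_nm = field, params = params)
}

#' Simulate a colocalized two-channel ground truth
#'
#' Builds two molecule channels (e.g. a ZO-1-like and a claudin-5-like label)
#' in the same field. A fraction `coloc_fraction` of channel-B molecules are
#' true partners of randomly chosen channel-A molecules, displaced by an
#' isotropic Gaussian of `partner_sigma_nm` (default 20 nm, so true partners
#' fall within the 90 nm colocalization radius with probability > 0.99); the
#' remainder of channel B is placed independently with `params_B`.
#'
#' @param geometry a [junction_geometry()].
#' @param params_A,params_B [clustering_params()] for the two channels.
#' @param coloc_fraction fraction of channel-B molecules that are true
#'   partners of a channel-A molecule, in `[0, 1]`.
#' @param partner_sigma_nm Gaussian SD of the partner displacement (nm).
#' @param seed integer RNG seed.
#' @return List with elements `A` and `B` ([place_fluorophores()] tables); `B`
#'   carries a `partner` column (index into `A`, `NA` for independent
#'   molecules).
#' @export
simulate_coloc_channels <- function(geometry, params_A, params_B,
                                    coloc_fraction = 0.4,
                                    partner_sigma_nm = 20, seed = 1L) {
  stopifnot(coloc_fraction >= 0, coloc_fraction <= 1, partner_sigma_nm > 0)
  A <- place_fluorophores(geometry, params_A, seed = seed)
  B <- place_fluorophores(geometry, params_B, seed = seed + 1L)
  set.seed(seed + 2L)
  nB <- nrow(B)
  k <- round(coloc_fraction * nB)
  B$partner <- NA_integer_
  if (k > 0L && nrow(A) > 0L) {
    which_b <- sample.int(nB, k)
    partner_a <- sample.int(nrow(A), k, replace = TRUE)
    off <- matrix(rnorm(2L * k, 0, partner_sigma_nm), ncol = 2)
    xy <- clamp_to_field(
      cbind(A$x_nm[partner_a] + off[, 1], A$y_nm[partner_a] + off[, 2]),
      attr(A, "field_size_nm"))
    B$x_nm[which_b] <- xy[, 1]
    B$y_nm[which_b] <- xy[, 2]
    B$cluster_id[which_b] <- -1L
    B$partner[which_b] <- partner_a
  }
  list(A = A, B = B)
}

#' Write ground-truth molecules to CSV
#'
#' @param molecules a `ground_truth_molecules` table (or a named list of them,
#'   one per channel).
#' @param path output CSV path; columns `x_nm`, `y_nm`, `channel`,
#'   `cluster_id`.
#' @return `path`, invisibly.
#' @export
write_ground_truth_csv <- function(molecules, path) {
  if (inherits(molecules, "ground_truth_molecules"))
    molecules <- list(A = molecules)
  df <- do.call(rbind, lapply(names(molecules), function(ch) {
    m <- molecules[[ch]]
    data.frame(x_nm = m$x_nm, y_nm = m$y_nm, channel = ch,
               cluster_id = m$cluster_id)
  }))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
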