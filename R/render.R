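# integrated Gaussian pixel weights for an emitter at (x0, y0) nm.
# Pixel (i, j) spans [(j-1)p, jp) x [(i-1)p, ip); weights integrate the PSF
# over each pixel, so photon mass is conserved up to window truncation.
psf_pixel_weights <- function(x0, y0, sigma, pixel_nm, nr, nc, reach_sigma = 5) {
  r_px <- ceiling(reach_sigma * sigma / pixel_nm)
  c0 <- floor(x0 / pixel_nm) + 1L
  r0 <- floor(y0 / pixel_nm) + 1L
  cols <- max(1L, c0 - r_px):min(nc, c0 + r_px)
  rows <- max(1L, r0 - r_px):min(nr, r0 + r_px)
  if (length(cols) == 0L || length(rows) == 0L) return(NULL)
  wx <- pnorm(cols * pixel_nm, x0, sigma) - pnorm((cols - 1) * pixel_nm, x0, sigma)
  wy <- pnorm(rows * pixel_nm, y0, sigma) - pnorm((rows - 1) * pixel_nm, y0, sigma)
  list(rows = rows, cols = cols, w = outer(wy, wx))
}

#' Render a blinking SMLM time-stack
#'
#' Simulates an EMCCD single-molecule movie of the ground-truth molecules:
#' each fluorophore is independently ON in each frame with probability
#' `on_probability`; ON emitters contribute an integrated 2D Gaussian PSF with
#' Poisson photon shot noise, scaled by the EM gain, on top of a constant
#' baseline with Gaussian read noise. Values are clipped to the 16-bit range
#' (a warning reports the number of saturated pixels).
#'
#' @param molecules a [place_fluorophores()] table.
#' @param acq an [acquisition_params()].
#' @param seed integer RNG seed.
#' @return An [image_stack()] of `n_frames` frames; attribute `on_events` is a
#'   data.frame (`frame`, `molecule`) of true emission events, and attribute
#'   `n_saturated` counts clipped pixels. With `shot_noise = FALSE` and zero
#'   read noise the noise-free expected image is returned unrounded.
#' @export
render_smlm_stack <- function(molecules, acq, seed = 1L) {
  stopifnot(inherits(molecules, "ground_truth_molecules"),
            inherits(acq, "acquisition_params"))
  set.seed(seed)
  field <- attr(molecules, "field_size_nm")
  nc <- ceiling(field[1] / acq$pixel_nm)
  nr <- ceiling(field[2] / acq$pixel_nm)
  n_mol <- nrow(molecules)
  stack <- array(0, c(nr, nc, acq$n_frames))
  noisy <- acq$shot_noise || acq$read_noise_adu > 0
  ev_frame <- integer(0); ev_mol <- integer(0)
  n_sat <- 0L

  # precompute each molecule's PSF footprint (position is frame-invariant)
  spots <- vector("list", n_mol)
  if (n_mol > 0L) {
    for (m in seq_len(n_mol)) {
      spots[[m]] <- psf_pixel_weights(molecules$x_nm[m], molecules$y_nm[m],
                                      acq$psf_sigma_nm, acq$pixel_nm, nr, nc)
    }
  }

  for (f in seq_len(acq$n_frames)) {
    frame <- matrix(acq$baseline_adu, nr, nc)
    if (acq$read_noise_adu > 0)
      frame <- frame + matrix(rnorm(nr * nc, 0, acq$read_noise_adu), nr, nc)
    on <- if (n_mol > 0L) which(runif(n_mol) < acq$on_probability) else integer(0)
    for (m in on) {
      sp <- spots[[m]]
      if (is.null(sp)) next
      lam <- acq$photons_per_on_frame * sp$w
      contrib <- if (acq$shot_noise) {
        matrix(rpois(length(lam), lam), nrow(lam)) * acq$em_gain
      } else lam * acq$em_gain
      frame[sp$rows, sp$cols] <- frame[sp$rows, sp$cols] + contrib
    }
    if (length(on)) {
      ev_frame <- c(ev_frame, rep.int(f, length(on)))
      ev_mol <- c(ev_mol, on)
    }
    if (noisy) frame <- round(frame)
    over <- frame > 65535
    if (any(over)) { n_sat <- n_sat + sum(over); frame[over] <- 65535 }
    frame[frame < 0] <- 0
    stack[, , f] <- frame
  }
  if (n_sat > 0L)
    warning(sprintf("%d pixel(s) saturated the 16-bit range and were clipped", n_sat))
  out <- image_stack(stack, acq$pixel_nm)
  attr(out, "on_events") <- data.frame(frame = ev_frame, molecule = ev_mol)
  attr(out, "n_saturated") <- n_sat
  out
}

# separable Gaussian blur with replicated edges
gauss_blur <- function(m, sigma_px) {
  if (sigma_px <= 0) return(m)
  r <- max(1L, ceiling(3 * sigma_px))
  k <- stats::dnorm(seq(-r, r), 0, sigma_px)
  k <- k / sum(k)
  blur_cols <- function(mat) {
    n <- nrow(mat)
    padded <- rbind(mat[rep(1L, r), , drop = FALSE], mat,
                    mat[rep(n, r), , drop = FALSE])
    f <- stats::filter(padded, k, sides = 2)
    matrix(f[(r + 1L):(r + n), ], n)
  }
  t(blur_cols(t(blur_cols(m))))
}

# default widefield background levels per substrate (ADU): coverglass lowest,
# polycarbonate intermediate, polyester highest autofluorescence
substrate_background_adu <- c(glass = 40, PC = 120, PE = 300)

#' Render a widefield immunofluorescence z-stack
#'
#' One in-focus slice carries the sharp junction-belt signal; slices above and
#' below carry increasingly Gaussian-blurred copies, on top of a
#' substrate-dependent additive background (coverglass < polycarbonate <
#' polyester) with Poisson noise.
#'
#' @param geometry a [junction_geometry()].
#' @param belt_intensity mean belt signal above background (ADU).
#' @param substrate `"glass"`, `"PC"` or `"PE"`.
#' @param n_slices number of z-slices (the in-focus slice is the middle one).
#' @param seed integer RNG seed.
#' @param pixel_nm widefield pixel pitch (nm).
#' @param belt_halfwidth_nm painted belt ribbon half-width (nm).
#' @param blur_per_slice_px defocus blur sigma added per slice of distance
#'   from focus (px).
#' @param noise logical; disable for the noise-free expected image.
#' @return An [image_stack()]; attribute `belt_mask` is the in-focus belt
#'   [roi_mask()], attribute `background_adu` the background level used.
#' @export
render_widefield_if <- function(geometry, belt_intensity,
                                substrate = c("glass", "PC", "PE"),
                                n_slices = 10L, seed = 1L, pixel_nm = 320,
                                belt_halfwidth_nm = 480,
                                blur_per_slice_px = 1.5, noise = TRUE) {
  substrate <- match.arg(substrate)
  stopifnot(n_slices >= 1, belt_intensity >= 0)
  set.seed(seed)
  bg <- substrate_background_adu[[substrate]]
  belt <- rasterize_belts(geometry, pixel_nm, belt_halfwidth_nm)
  signal <- belt$mask * belt_intensity
  focus <- ceiling(n_slices / 2)
  nr <- nrow(belt$mask); nc <- ncol(belt$mask)
  stack <- array(0, c(nr, nc, n_slices))
  for (k in seq_len(n_slices)) {
    sl <- bg + gauss_blur(signal, blur_per_slice_px * abs(k - focus))
    if (noise) sl <- matrix(rpois(length(sl), sl), nr, nc)
    sl[sl > 65535] <- 65535
    stack[, , k] <- sl
  }
  out <- image_stack(stack, pixel_nm, channel = NA, substrate = substrate)
  attr(out, "belt_mask") <- belt
  attr(out, "background_adu") <- bg
  attr(out, "focus_slice") <- focus
  out
}
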