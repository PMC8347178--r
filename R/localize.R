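#' Robust per-frame background estimation
#'
#' Median background level and a robust noise SD (1.4826 x median absolute
#' deviation), insensitive to the sparse bright emitters that sit on top of
#' the background in a blinking movie. This gives the detection rule
#' "threshold of 3" its operational meaning: candidates must exceed
#' `bg_level + 3 * noise_sd`.
#'
#' @param frame 2D matrix.
#' @return List with `bg_level`, `noise_sd` and `flagged` (TRUE for a
#'   constant frame, where the noise SD is 0).
#' @export
estimate_background <- function(frame) {
  if (length(frame) == 0L) stop("empty frame")
  bg <- median(frame)
  ns <- mad(frame)                       # constant = 1.4826 by default
  list(bg_level = bg, noise_sd = ns, flagged = ns == 0)
}

# strict 8-neighbourhood local maxima
local_maxima <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  pad <- matrix(-Inf, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- m
  res <- matrix(TRUE, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    res <- res & (m > pad[(2:(nr + 1L)) + dr, (2:(nc + 1L)) + dc])
  }
  res
}

#' Detect candidate emitters in one frame
#'
#' The frame is matched-filtered with a small Gaussian (`smooth_sigma_px`),
#' then candidate pixels are strict local maxima in their 8-neighbourhood
#' that exceed `bg_level + threshold_factor * noise_sd`, with background and
#' noise estimated robustly from the raw frame. Candidates closer than half
#' a fit window are merged, keeping the brighter one.
#'
#' @param frame 2D matrix.
#' @param params a [detection_params()].
#' @param background optional precomputed [estimate_background()] result.
#' @return Integer matrix with columns `row`, `col` (possibly 0 rows).
#' @export
detect_candidates <- function(frame, params, background = NULL) {
  if (is.null(background)) background <- estimate_background(frame)
  thr <- background$bg_level + params$threshold_factor * background$noise_sd
  sm <- if (params$smooth_sigma_px > 0)
    gauss_blur(frame, params$smooth_sigma_px) else frame
  cand <- which(local_maxima(sm) & sm > thr, arr.ind = TRUE)
  colnames(cand) <- c("row", "col")
  if (nrow(cand) <= 1L) return(cand)
  o <- order(frame[cand], decreasing = TRUE)
  cand <- cand[o, , drop = FALSE]
  min_d2 <- (params$fit_window_px / 2)^2
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    ok <- TRUE
    if (any(keep)) {
      kept <- cand[keep, , drop = FALSE]
      d2 <- (kept[, 1] - cand[i, 1])^2 + (kept[, 2] - cand[i, 2])^2
      ok <- all(d2 >= min_d2)
    }
    keep[i] <- ok
  }
  cand[keep, , drop = FALSE]
}

#' Fit a 2D Gaussian to a candidate emitter
#'
#' Levenberg-Marquardt least squares of
#' `offset + amplitude * exp(-((x - x0)^2 + (y - y0)^2) / (2 sigma^2))`
#' over the fit window, in pixel-centre coordinates (pixel `(i, j)` spans
#' `[(j-1)p, jp) x [(i-1)p, ip)` nm, so its centre is `(j - 0.5, i - 0.5)`
#' px). Position uncertainties come from the fit's parameter covariance.
#'
#' @param frame 2D matrix.
#' @param peak integer `c(row, col)` candidate pixel; the fit window must lie
#'   inside the frame.
#' @param params a [detection_params()].
#' @param pixel_nm camera pixel pitch (nm).
#' @param noise_sd optional robust noise SD of the frame; when given, fits
#'   whose amplitude does not exceed `threshold_factor * noise_sd` are
#'   rejected (the detection threshold applied to the fitted peak height, so
#'   noise spikes that converge to a shallow blob are discarded).
#' @return A list `list(record = <one-row data.frame> or NULL,
#'   reason = <character> or NA)`. Rejection reasons: `nonconvergence`,
#'   `sigma_out_of_range`, `center_out_of_window`, `singular_covariance`,
#'   `nonpositive_amplitude`, `amplitude_below_threshold`.
#' @export
fit_gaussian_2d <- function(frame, peak, params, pixel_nm, noise_sd = NULL) {
  half <- (params$fit_window_px - 1L) %/% 2L
  r0 <- unname(peak[1]); c0 <- unname(peak[2])
  if (r0 - half < 1L || r0 + half > nrow(frame) ||
      c0 - half < 1L || c0 + half > ncol(frame))
    stop("fit window does not lie inside the frame")
  rows <- (r0 - half):(r0 + half)
  cols <- (c0 - half):(c0 + half)
  z <- frame[rows, cols]
  xs <- cols - 0.5; ys <- rows - 0.5          # pixel-centre coordinates (px)
  X <- matrix(xs, length(ys), length(xs), byrow = TRUE)
  Y <- matrix(ys, length(ys), length(xs))
  sig0 <- params$psf_sigma_nm / pixel_nm

  model <- function(p) {
    p[1] + p[2] * exp(-((X - p[3])^2 + (Y - p[4])^2) / (2 * p[5]^2))
  }
  start <- c(offset = min(z), amplitude = max(z) - min(z),
             x0 = c0 - 0.5, y0 = r0 - 0.5, sigma = sig0)
  # non-convergence is detected from the info code, so the optimizer's own
  # warnings are redundant noise here
  fit <- tryCatch(
    suppressWarnings(
      minpack.lm::nls.lm(par = start, fn = function(p) as.vector(z - model(p)),
                         control = minpack.lm::nls.lm.control(
                           maxiter = params$max_iterations,
                           ftol = params$convergence_tol))),
    error = function(e) NULL)
  reject <- function(reason) list(record = NULL, reason = reason)
  if (is.null(fit) || !fit$info %in% 1:4) return(reject("nonconvergence"))
  p <- fit$par
  if (any(!is.finite(p))) return(reject("nonconvergence"))
  if (p["amplitude"] <= 0) return(reject("nonpositive_amplitude"))
  if (!is.null(noise_sd) && p["amplitude"] <= params$threshold_factor * noise_sd)
    return(reject("amplitude_below_threshold"))
  s <- abs(p[["sigma"]])
  if (s < 0.5 * sig0 || s > 3 * sig0) return(reject("sigma_out_of_range"))
  if (p["x0"] < min(xs) - 0.5 || p["x0"] > max(xs) + 0.5 ||
      p["y0"] < min(ys) - 0.5 || p["y0"] > max(ys) + 0.5)
    return(reject("center_out_of_window"))
  dof <- length(z) - 5L
  covm <- tryCatch(fit$deviance / dof * solve(fit$hessian),
                   error = function(e) NULL)
  if (is.null(covm) || any(!is.finite(diag(covm))) || any(diag(covm) < 0))
    return(reject("singular_covariance"))
  err <- sqrt(diag(covm))
  rec <- data.frame(
    frame = NA_integer_,
    x_nm = p[["x0"]] * pixel_nm, y_nm = p[["y0"]] * pixel_nm,
    amplitude = p[["amplitude"]], sigma_nm = s * pixel_nm,
    offset = p[["offset"]],
    err_x_nm = max(err[["x0"]] * pixel_nm, 1e-9),
    err_y_nm = max(err[["y0"]] * pixel_nm, 1e-9))
  list(record = rec, reason = NA_character_)
}

#' Localize all emitters in a blinking time-stack
#'
#' Discards the first `discard_frames` frames, then per remaining frame:
#' robust background estimation, candidate detection at
#' `threshold_factor` robust noise SDs, and 2D Gaussian sub-pixel fitting of
#' each candidate. Accepted fits are concatenated into a localization table;
#' rejected fits are logged with reason codes.
#'
#' @param stack an [image_stack()] time-stack.
#' @param params a [detection_params()].
#' @param channel optional channel label carried into the table.
#' @return A [loc_table()]; attribute `rejections` is a data.frame (`frame`,
#'   `row`, `col`, `reason`), attribute `field_size_nm` the rendered field.
#' @export
localize_stack <- function(stack, params = detection_params(),
                           channel = NA) {
  stopifnot(inherits(stack, "image_stack"))
  nf <- n_slices(stack)
  if (nf <= params$discard_frames)
    stop(sprintf("stack has %d frames but discard_frames = %d",
                 nf, params$discard_frames))
  half <- (params$fit_window_px - 1L) %/% 2L
  recs <- list(); rej <- list()
  for (f in (params$discard_frames + 1L):nf) {
    frame <- stack$data[, , f]
    bg <- estimate_background(frame)
    cand <- detect_candidates(frame, params, bg)
    for (k in seq_len(nrow(cand))) {
      r0 <- cand[k, 1]; c0 <- cand[k, 2]
      if (r0 - half < 1L || r0 + half > nrow(frame) ||
          c0 - half < 1L || c0 + half > ncol(frame)) {
        rej[[length(rej) + 1L]] <- data.frame(frame = f, row = r0, col = c0,
                                              reason = "window_outside_frame")
        next
      }
      res <- fit_gaussian_2d(frame, c(r0, c0), params, stack$pixel_nm,
                             noise_sd = bg$noise_sd)
      if (is.null(res$record)) {
        rej[[length(rej) + 1L]] <- data.frame(frame = f, row = r0, col = c0,
                                              reason = res$reason)
      } else {
        res$record$frame <- f
        recs[[length(recs) + 1L]] <- res$record
      }
    }
  }
  records <- if (length(recs)) do.call(rbind, recs) else
    data.frame(frame = integer(0), x_nm = numeric(0), y_nm = numeric(0),
               amplitude = numeric(0), sigma_nm = numeric(0),
               offset = numeric(0), err_x_nm = numeric(0),
               err_y_nm = numeric(0))
  rejections <- if (length(rej)) do.call(rbind, rej) else
    data.frame(frame = integer(0), row = integer(0), col = integer(0),
               reason = character(0))
  out <- loc_table(records, pixel_nm = stack$pixel_nm, channel = channel,
                   rejections = rejections)
  attr(out, "field_size_nm") <- c(ncol(frame), nrow(frame)) * stack$pixel_nm
  out
}

#' Restrict a localization table to an ROI mask
#'
#' Keeps records whose fitted position falls inside a true mask pixel and
#' records the analysed area, enabling area-normalized density comparisons.
#'
#' @param table a [loc_table()].
#' @param roi an [roi_mask()] on the same coordinate frame.
#' @return The masked [loc_table()] with `roi_area_nm2` set.
#' @export
apply_mask <- function(table, roi) {
  stopifnot(inherits(table, "loc_table"), inherits(roi, "roi_mask"))
  if (!any(roi$mask)) stop("empty mask")
  col <- floor(table$x_nm / roi$pixel_nm) + 1L
  row <- floor(table$y_nm / roi$pixel_nm) + 1L
  inside <- row >= 1L & row <= nrow(roi$mask) & col >= 1L & col <= ncol(roi$mask)
  inside[inside] <- roi$mask[cbind(row[inside], col[inside])]
  out <- loc_table(as.data.frame(table)[inside, , drop = FALSE],
                   pixel_nm = attr(table, "pixel_nm"),
                   channel = attr(table, "channel"),
                   roi_area_nm2 = roi_area_nm2(roi),
                   rejections = attr(table, "rejections"))
  attr(out, "field_size_nm") <- attr(table, "field_size_nm")
  out
}

#' Localization density in molecules per nm^2
#'
#' Event-level density: localization count divided by the analysed ROI area.
#' Repeated blinks of one fluorophore are not merged, so absolute values are
#' event densities, comparable across conditions at matched acquisition
#' settings.
#'
#' @param table a [loc_table()] with `roi_area_nm2` set (see [apply_mask()]).
#' @return Density in molecules/nm^2.
#' @export
loc_density <- function(table) {
  a <- attr(table, "roi_area_nm2")
  if (!is.finite(a) || a <= 0)
    stop("roi_area_nm2 is unset; apply a mask first")
  nrow(table) / a
}

#' Render a pointillist image from a localization table
#'
#' 2D histogram of the fitted positions at `render_pixel_nm`, optionally
#' convolved with a Gaussian. The pre-blur histogram total equals the record
#' count.
#'
#' @param table a [loc_table()].
#' @param render_pixel_nm rendering pixel pitch (nm).
#' @param blur_sigma_nm optional Gaussian blur SD (nm); 0 disables.
#' @param field_size_nm optional `c(width, height)` nm; defaults to the
#'   table's rendered field or the positions' bounding box.
#' @return Matrix image.
#' @export
render_pointillist <- function(table, render_pixel_nm = 20,
                               blur_sigma_nm = 0, field_size_nm = NULL) {
  stopifnot(render_pixel_nm > 0)
  if (is.null(field_size_nm)) field_size_nm <- attr(table, "field_size_nm")
  if (is.null(field_size_nm))
    field_size_nm <- c(max(table$x_nm, 1), max(table$y_nm, 1))
  nc <- max(1L, ceiling(field_size_nm[1] / render_pixel_nm))
  nr <- max(1L, ceiling(field_size_nm[2] / render_pixel_nm))
  img <- matrix(0, nr, nc)
  if (nrow(table) > 0) {
    col <- pmin(pmax(floor(table$x_nm / render_pixel_nm) + 1L, 1L), nc)
    row <- pmin(pmax(floor(table$y_nm / render_pixel_nm) + 1L, 1L), nr)
    for (i in seq_along(row)) img[row[i], col[i]] <- img[row[i], col[i]] + 1
  }
  if (blur_sigma_nm > 0) img <- gauss_blur(img, blur_sigma_nm / render_pixel_nm)
  img
}
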