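#' Binary region-of-interest mask
#'
#' @param mask logical (or 0/1) matrix; `TRUE` pixels belong to the ROI.
#' @param pixel_nm pixel pitch in nm.
#' @return An object of class `roi_mask`.
#' @export
roi_mask <- function(mask, pixel_nm) {
  stopifnot(is.matrix(mask), pixel_nm > 0)
  structure(list(mask = mask != 0, pixel_nm = as.numeric(pixel_nm)),
            class = "roi_mask")
}

#' ROI area in nm^2
#' @param roi an [roi_mask()].
#' @return true-pixel count times pixel area.
#' @export
roi_area_nm2 <- function(roi) {
  sum(roi$mask) * roi$pixel_nm^2
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("roi_mask: %d x %d px at %.0f nm/px, %d true px (%.3g um^2)\n",
              nrow(x$mask), ncol(x$mask), x$pixel_nm, sum(x$mask),
              roi_area_nm2(x) / 1e6))
  invisible(x)
}

#' Grey-scale image stack
#'
#' Container for widefield z-stacks and SMLM time-stacks: a numeric array
#' `[row, col, slice]` of non-negative 16-bit intensities plus pixel pitch and
#' channel metadata. Slices are z-planes for widefield data and time frames
#' for SMLM movies.
#'
#' @param data numeric array `rows x cols x slices` (a matrix is promoted to
#'   one slice).
#' @param pixel_nm pixel pitch in nm.
#' @param channel optional channel label (e.g. excitation wavelength).
#' @param substrate optional substrate label: `"glass"`, `"PC"` or `"PE"`.
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(data, pixel_nm, channel = NA, substrate = NA) {
  if (is.matrix(data)) data <- array(data, c(dim(data), 1L))
  stopifnot(length(dim(data)) == 3, pixel_nm > 0)
  if (min(data) < 0 || max(data) > 65535)
    stop("intensities must lie within the 16-bit range")
  structure(list(data = data, pixel_nm = as.numeric(pixel_nm),
                 channel = channel, substrate = substrate),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("image_stack: %d x %d px, %d slice(s), %.0f nm/px\n",
              d[1], d[2], d[3], x$pixel_nm))
  invisible(x)
}

#' Number of slices/frames in a stack
#' @param stack an [image_stack()].
#' @return integer slice count.
#' @export
n_slices <- function(stack) dim(stack$data)[3]

#' Localization table
#'
#' Per-molecule localization records produced by [localize_stack()]: frame
#' index, fitted position in nm, amplitude above local offset (ADU), fitted
#' PSF width, local background offset, and position uncertainties from the
#' fit covariance.
#'
#' @param records data.frame with columns `frame`, `x_nm`, `y_nm`,
#'   `amplitude`, `sigma_nm`, `offset`, `err_x_nm`, `err_y_nm`.
#' @param pixel_nm camera pixel pitch in nm.
#' @param channel optional channel label.
#' @param roi_area_nm2 analysed area in nm^2, set by [apply_mask()].
#' @param rejections optional data.frame logging rejected fits with a
#'   `reason` column.
#' @return An object of class `loc_table` (also a data.frame).
#' @export
loc_table <- function(records, pixel_nm, channel = NA,
                      roi_area_nm2 = NA_real_, rejections = NULL) {
  cols <- c("frame", "x_nm", "y_nm", "amplitude", "sigma_nm", "offset",
            "err_x_nm", "err_y_nm")
  if (nrow(records) == 0L) {
    records <- as.data.frame(setNames(rep(list(numeric(0)), length(cols)), cols))
  }
  stopifnot(all(cols %in% names(records)))
  if (nrow(records) > 0) {
    stopifnot(all(records$err_x_nm > 0), all(records$err_y_nm > 0),
              all(records$amplitude > 0))
  }
  structure(records[cols], class = c("loc_table", "data.frame"),
            pixel_nm = as.numeric(pixel_nm), channel = channel,
            roi_area_nm2 = roi_area_nm2, rejections = rejections,
            row.names = seq_len(nrow(records)))
}

#' @export
print.loc_table <- function(x, ...) {
  cat(sprintf("loc_table: %d localizations (channel %s, %.0f nm/px",
              nrow(x), as.character(attr(x, "channel")), attr(x, "pixel_nm")))
  a <- attr(x, "roi_area_nm2")
  if (is.finite(a)) cat(sprintf(", ROI %.3g um^2", a / 1e6))
  cat(")\n")
  if (nrow(x) > 0) print.data.frame(head(as.data.frame(x), 5))
  invisible(x)
}

#' Write / read a localization table as CSV
#'
#' @param table a [loc_table()].
#' @param path output CSV path.
#' @return `write_loc_csv` returns `path` invisibly; `read_loc_csv` returns a
#'   [loc_table()].
#' @export
write_loc_csv <- function(table, path) {
  write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_loc_csv
#' @param pixel_nm,channel metadata to attach on read.
#' @export
read_loc_csv <- function(path, pixel_nm, channel = NA) {
  loc_table(read.csv(path), pixel_nm = pixel_nm, channel = channel)
}
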