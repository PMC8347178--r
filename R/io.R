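#' Write an image stack as a multi-page 16-bit grey-scale TIFF
#'
#' @param stack an [image_stack()] (or matrix / 3D array).
#' @param path output TIFF path.
#' @return `path`, invisibly. Values are rounded to integers on write.
#' @export
write_stack_tiff <- function(stack, path) {
  data <- if (inherits(stack, "image_stack")) stack$data else stack
  if (is.matrix(data)) data <- array(data, c(dim(data), 1L))
  pages <- lapply(seq_len(dim(data)[3]), function(k) {
    m <- round(data[, , k])
    m[m < 0] <- 0; m[m > 65535] <- 65535
    m / 65535
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a multi-page grey-scale TIFF as an image stack
#'
#' @param path TIFF path.
#' @param pixel_nm pixel pitch metadata to attach.
#' @param channel,substrate optional metadata.
#' @return An [image_stack()].
#' @export
read_stack_tiff <- function(path, pixel_nm, channel = NA, substrate = NA) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (is.matrix(pages)) pages <- list(pages)
  data <- array(0, c(dim(pages[[1]]), length(pages)))
  for (k in seq_along(pages)) data[, , k] <- pages[[k]]
  image_stack(data, pixel_nm, channel = channel, substrate = substrate)
}

#' Write / read a binary ROI mask as an 8-bit TIFF (0/255)
#'
#' @param roi an [roi_mask()].
#' @param path TIFF path.
#' @return `write_mask_tiff` returns `path` invisibly; `read_mask_tiff` an
#'   [roi_mask()].
#' @export
write_mask_tiff <- function(roi, path) {
  tiff::writeTIFF(roi$mask * 1.0, path, bits.per.sample = 8L)
  invisible(path)
}

#' @rdname write_mask_tiff
#' @param pixel_nm pixel pitch metadata to attach on read.
#' @export
read_mask_tiff <- function(path, pixel_nm) {
  m <- tiff::readTIFF(path, as.is = TRUE)
  roi_mask(m > 0, pixel_nm)
}

#' Echo generation/analysis parameters to a JSON sidecar
#'
#' @param params named list of parameters (nested lists allowed).
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_params_json <- function(params, path) {
  jsonlite::write_json(params, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}
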