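# Mask and grayscale image I/O (8/16-bit PNG or TIFF chosen by extension).
# Images are matrices with rows = y, columns = x, intensities in [0, 1].

read_raster_file <- function(path) {
  if (!file.exists(path)) oc_stop("shape_error", "image not found: %s", path)
  img <- if (grepl("\\.tiff?$", path, ignore.case = TRUE))
    tiff::readTIFF(path) else png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  img
}

write_raster_file <- function(img, path) {
  img <- pmin(pmax(img, 0), 1)
  if (grepl("\\.tiff?$", path, ignore.case = TRUE))
    tiff::writeTIFF(img, path, bits.per.sample = 8L)
  else png::writePNG(img, path)
  invisible(path)
}

#' Read a binary mask from a PNG/TIFF image
#'
#' Any nonzero pixel is true. The image dimensions must match the frame.
#'
#' @param path PNG or TIFF file.
#' @param frame the [image_frame] the mask realizes.
#' @return a [binary_mask].
#' @export
read_mask_image <- function(path, frame) {
  img <- read_raster_file(path)
  if (nrow(img) != frame$height || ncol(img) != frame$width)
    oc_stop("shape_error",
            "mask image %dx%d does not match frame %dx%d",
            nrow(img), ncol(img), frame$height, frame$width)
  binary_mask(img > 0, frame)
}

#' Write a binary mask as an 8-bit PNG/TIFF image
#'
#' Lossless boolean round-trip with [read_mask_image()].
#'
#' @param mask a [binary_mask].
#' @param path output path (.png/.tif/.tiff).
#' @return `path`, invisibly.
#' @export
write_mask_image <- function(mask, path) {
  stopifnot(inherits(mask, "binary_mask"))
  write_raster_file(mask$grid * 1, path)
}
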