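#' Imaging modalities
#'
#' Frame modalities handled by the pipeline: the choriocapillaris slab of
#' swept-source OCT angiography, and early/mid-phase indocyanine green
#' angiography frames.
#' @export
MODALITIES <- c("OCTA_CHORIOCAPILLARIS", "ICGA_EARLY", "ICGA_MID")

#' Lesion taxonomy
#'
#' Five annotation classes: the OCTA choriocapillaris taxonomy (`TYPE_A`
#' coarse granulated hyper-reflective area, `TYPE_B` roundish dark halo
#' around type A, `TYPE_C` coarse granulated hypo-reflective spots), plus the
#' ICGA classes (`HYPERFLUORESCENCE` on mid-phase frames, `HYPOFLUORESCENCE`
#' on early-phase frames).
#' @export
LESION_TYPES <- c("TYPE_A", "TYPE_B", "TYPE_C",
                  "HYPERFLUORESCENCE", "HYPOFLUORESCENCE")

#' Define an image frame
#'
#' An `image_frame` couples a pixel grid to its physical field of view, which
#' fixes the px -> mm^2 conversion used by all area reporting. Coordinates are
#' 0-based with x rightward and y downward; pixel centers sit at integer
#' coordinates, so pixel (0,0) spans `[-0.5, 0.5)^2`.
#'
#' @param width,height pixel counts (>= 1).
#' @param fov_width,fov_height physical field of view in mm (> 0).
#' @param modality one of [MODALITIES].
#' @return an object of class `image_frame`.
#' @examples
#' fr <- image_frame(1024, 1024, 12, 12, "OCTA_CHORIOCAPILLARIS")
#' px_area_mm2(fr) * 1024^2  # total fov area, 144 mm^2
#' @export
image_frame <- function(width, height, fov_width, fov_height,
                        modality = "OCTA_CHORIOCAPILLARIS") {
  if (!is_finite_num(c(width, height)) || width < 1 || height < 1)
    oc_stop("configuration_error", "frame dimensions must be >= 1 px")
  if (!is_finite_num(c(fov_width, fov_height)) ||
      fov_width <= 0 || fov_height <= 0)
    oc_stop("configuration_error", "field of view must be positive (mm)")
  modality <- match.arg(modality, MODALITIES)
  structure(list(width = as.integer(width), height = as.integer(height),
                 fov_width = fov_width, fov_height = fov_height,
                 modality = modality),
            class = "image_frame")
}

#' Physical area of one pixel
#'
#' @param frame an [image_frame].
#' @return pixel area in mm^2.
#' @export
px_area_mm2 <- function(frame) {
  stopifnot(inherits(frame, "image_frame"))
  (frame$fov_width / frame$width) * (frame$fov_height / frame$height)
}

#' @export
print.image_frame <- function(x, ...) {
  cat(sprintf("<image_frame> %dx%d px, %.3gx%.3g mm, %s\n",
              x$width, x$height, x$fov_width, x$fov_height, x$modality))
  invisible(x)
}

#' Read frame metadata from a JSON or YAML config
#'
#' Frame metadata (pixel size and field of view) is always user-supplied,
#' never inferred from image files.
#'
#' @param path path to a `.json`, `.yaml` or `.yml` file with fields
#'   `width`, `height`, `fov_width_mm`, `fov_height_mm`, `modality`.
#' @return an [image_frame].
#' @export
read_frame_config <- function(path) {
  if (!file.exists(path))
    oc_stop("configuration_error", "frame config not found: %s", path)
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      oc_stop("configuration_error", "yaml package required for %s", path)
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("width", "height", "fov_width_mm", "fov_height_mm"))
    if (is.null(cfg[[f]]))
      oc_stop("configuration_error", "frame config missing field '%s'", f)
  image_frame(cfg$width, cfg$height, cfg$fov_width_mm, cfg$fov_height_mm,
              cfg$modality %||% "OCTA_CHORIOCAPILLARIS")
}
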