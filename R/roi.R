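#' Construct a region of interest
#'
#' A `roi` is a planar region given by one or more polygon rings under the
#' even-odd fill rule (the semantics of ImageJ composite selections): a point
#' is inside the region when it is inside an odd number of rings. Holes and
#' disjoint components are therefore both expressed by extra rings. One ROI
#' may hold several disjoint components (e.g. multifocal type C spots); its
#' area is the even-odd total.
#'
#' @param rings a list of rings; each ring is a list/data.frame with numeric
#'   `x` and `y` of equal length >= 3 (implicitly closed). A single ring may
#'   be given directly.
#' @param label optional lesion class, one of [LESION_TYPES].
#' @param grader optional grader identifier.
#' @param frame optional [image_frame] the coordinates refer to.
#' @return an object of class `roi`.
#' @examples
#' r <- roi(list(x = c(0, 4, 0), y = c(0, 0, 3)), label = "TYPE_A")
#' polygon_area_px(r)  # 6
#' @export
roi <- function(rings, label = NULL, grader = NULL, frame = NULL) {
  if (!is.null(rings$x)) rings <- list(rings)
  if (!is.list(rings) || length(rings) < 1)
    oc_stop("invalid_roi_error", "an ROI needs at least one ring")
  rings <- lapply(rings, function(r) {
    x <- as.numeric(r$x); y <- as.numeric(r$y)
    if (length(x) != length(y) || length(x) < 3)
      oc_stop("invalid_roi_error", "every ring needs >= 3 (x, y) vertices")
    if (!all(is.finite(x)) || !all(is.finite(y)))
      oc_stop("invalid_roi_error", "ring vertices must be finite")
    list(x = x, y = y)
  })
  if (!is.null(label)) label <- match.arg(label, LESION_TYPES)
  structure(list(rings = rings, label = label, grader = grader,
                 frame = frame),
            class = "roi")
}

#' @export
print.roi <- function(x, ...) {
  cat(sprintf("<roi> %d ring(s), %s vertices, label=%s, grader=%s\n",
              length(x$rings),
              paste(vapply(x$rings, function(r) length(r$x), 1L),
                    collapse = "+"),
              x$label %||% "<none>", x$grader %||% "<none>"))
  invisible(x)
}

#' Bundle annotations for one eye and visit
#'
#' @param eye_id eye identifier.
#' @param timepoint ordinal visit index, 0 = baseline.
#' @param group treatment arm, `"LASER"` or `"OBSERVATION"` (or `NA`).
#' @param grader grader identifier applied to all `rois` lacking one.
#' @param rois list of [roi] objects; at most one per lesion label.
#' @return an object of class `annotation_set`.
#' @export
annotation_set <- function(eye_id, timepoint = 0L, group = NA_character_,
                           grader = "g1", rois = list()) {
  if (timepoint < 0) oc_stop("invalid_roi_error", "timepoint must be >= 0")
  if (!is.na(group)) group <- match.arg(group, c("LASER", "OBSERVATION"))
  rois <- lapply(rois, function(r) {
    stopifnot(inherits(r, "roi"))
    if (is.null(r$grader)) r$grader <- grader
    r
  })
  labs <- vapply(rois, function(r) r$label %||% NA_character_, "")
  if (anyDuplicated(labs[!is.na(labs)]))
    oc_stop("invalid_roi_error",
            "at most one ROI per lesion label per annotation set")
  structure(list(eye_id = eye_id, timepoint = as.integer(timepoint),
                 group = group, grader = grader, rois = rois),
            class = "annotation_set")
}

#' Fetch the ROI with a given label from an annotation set
#'
#' @param set an [annotation_set].
#' @param label a lesion label.
#' @param required error (class `missing_annotation_error`) when absent?
#' @return a [roi] or `NULL`.
#' @export
get_roi <- function(set, label, required = TRUE) {
  stopifnot(inherits(set, "annotation_set"))
  label <- match.arg(label, LESION_TYPES)
  for (r in set$rois) if (identical(r$label, label)) return(r)
  if (required)
    oc_stop("missing_annotation_error",
            "annotation set for eye %s (t=%d, grader %s) lacks label %s",
            set$eye_id, set$timepoint, set$grader, label)
  NULL
}
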