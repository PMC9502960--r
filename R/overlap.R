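# Overlap metrics between co-registered annotations. Two engines:
#  RASTER  — counts on the fixed frame's pixel-center rasterization, the
#            primary method (annotations are pixel-resolution ImageJ ROIs);
#  POLYGON — exact clipping (polyclip/Clipper), retained as the oracle.

clip_rings_area <- function(rings) {
  if (!length(rings)) return(0)
  abs(sum(vapply(rings, ring_signed_area, 0)))
}

overlap_result <- function(area_a_px, area_b_px, inter_px, union_px,
                           method, frame, meta = list()) {
  if (union_px <= 0)
    oc_stop("undefined_overlap_error",
            "union of the two annotations is empty; Jaccard index undefined")
  s <- px_area_mm2(frame)
  structure(list(area_a_px = area_a_px, area_b_px = area_b_px,
                 intersection_px = inter_px, union_px = union_px,
                 area_a_mm2 = area_a_px * s, area_b_mm2 = area_b_px * s,
                 intersection_mm2 = inter_px * s, union_mm2 = union_px * s,
                 jaccard = inter_px / union_px,
                 method = method, meta = meta),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf(
    "<overlap %s> |A|=%.4g |B|=%.4g |A&B|=%.4g |A|B|=%.4g mm2, JI=%.4f\n",
    x$method, x$area_a_mm2, x$area_b_mm2, x$intersection_mm2, x$union_mm2,
    x$jaccard))
  invisible(x)
}

#' Jaccard index of two ROIs on a common frame
#'
#' Computes |A n B| / |A u B| for two annotations already expressed in the
#' same (fixed) frame coordinates — apply registration first. The RASTER
#' method counts pixel centers on the frame grid; the POLYGON method clips
#' the even-odd polygon fills exactly. Symmetric in its arguments.
#'
#' @param a,b [roi] objects in the frame's coordinates.
#' @param frame the fixed [image_frame] (defines both the raster grid and
#'   the mm^2 scale).
#' @param method `"RASTER"` (default) or `"POLYGON"`.
#' @param supersample integer >= 1; for RASTER, rasterize on a grid this
#'   many times finer than the frame (used by oracle comparisons).
#' @return an `overlap_result` with areas (px^2 and mm^2), intersection,
#'   union, and `jaccard` in `[0, 1]`. An empty union raises
#'   `undefined_overlap_error`.
#' @examples
#' fr <- image_frame(64, 64, 6, 6)
#' sq <- function(x0) roi(list(x = c(x0, x0 + 10, x0 + 10, x0),
#'                             y = c(10, 10, 20, 20)))
#' jaccard_index(sq(10), sq(15), fr, method = "POLYGON")$jaccard  # 1/3
#' @export
jaccard_index <- function(a, b, frame, method = c("RASTER", "POLYGON"),
                          supersample = 1L) {
  stopifnot(inherits(a, "roi"), inherits(b, "roi"),
            inherits(frame, "image_frame"))
  method <- match.arg(method)
  if (method == "POLYGON") {
    # eps pins the clipper's integer grid to 1e-10 px so results are stable
    # under similarity transforms well below the 1e-9 tolerance
    inter <- polyclip::polyclip(a$rings, b$rings, op = "intersection",
                                fillA = "evenodd", fillB = "evenodd",
                                eps = 1e-10)
    uni <- polyclip::polyclip(a$rings, b$rings, op = "union",
                              fillA = "evenodd", fillB = "evenodd",
                              eps = 1e-10)
    inter_px <- if (length(inter))
      abs(sum(vapply(inter, ring_signed_area, 0))) else 0
    union_px <- if (length(uni))
      abs(sum(vapply(uni, ring_signed_area, 0))) else 0
    return(overlap_result(polygon_area_px(a), polygon_area_px(b),
                          inter_px, union_px, "POLYGON", frame))
  }
  rframe <- frame
  ss <- as.integer(supersample)
  if (ss > 1) {
    rframe <- image_frame(frame$width * ss, frame$height * ss,
                          frame$fov_width, frame$fov_height, frame$modality)
    scale_up <- function(r) {
      roi(lapply(r$rings,
                 function(rr) list(x = rr$x * ss + (ss - 1) / 2,
                                   y = rr$y * ss + (ss - 1) / 2)),
          label = r$label, grader = r$grader)
    }
    a <- scale_up(a); b <- scale_up(b)
  }
  ma <- roi_to_mask(a, rframe)$grid
  mb <- roi_to_mask(b, rframe)$grid
  f <- 1 / ss^2  # supersampled cell count back to frame px^2
  overlap_result(sum(ma) * f, sum(mb) * f,
                 sum(ma & mb) * f, sum(ma | mb) * f, "RASTER", frame)
}

#' Cross-modality lesion concordance for one eye
#'
#' The spatial overlap between the type A (coarse granulated hyper-
#' reflective) annotation on the OCTA choriocapillaris slab and the
#' hyperfluorescence annotation on mid-phase ICGA, after mapping the ICGA
#' annotation onto the fixed OCTA grid through the registration transform.
#'
#' @param octa_set [annotation_set] containing a `TYPE_A` ROI.
#' @param icga_set [annotation_set] containing a `HYPERFLUORESCENCE` ROI,
#'   same grader/eye/timepoint.
#' @param t [affine_transform] mapping ICGA (moving) to OCTA (fixed).
#' @param frame the fixed OCTA [image_frame].
#' @param method overlap engine, see [jaccard_index()].
#' @return an `overlap_result`; `meta` records eye, timepoint, grader.
#' @export
crossmodal_concordance <- function(octa_set, icga_set, t, frame,
                                   method = "RASTER") {
  a <- get_roi(octa_set, "TYPE_A")
  h <- get_roi(icga_set, "HYPERFLUORESCENCE")
  res <- jaccard_index(a, apply_to_roi(t, h, frame), frame, method)
  res$meta <- list(eye_id = octa_set$eye_id, timepoint = octa_set$timepoint,
                   grader = octa_set$grader, comparison = "crossmodal",
                   label = "TYPE_A_vs_HYPERFLUORESCENCE")
  res
}

#' Interobserver agreement for one lesion label
#'
#' Jaccard index between two graders' annotations of the same label on the
#' same frame; no registration is applied.
#'
#' @param set_g1,set_g2 [annotation_set]s from two different graders for the
#'   same eye/timepoint.
#' @param frame the common [image_frame].
#' @param label lesion label to compare.
#' @param method overlap engine, see [jaccard_index()].
#' @return an `overlap_result`; `meta` records both graders.
#' @export
interobserver_agreement <- function(set_g1, set_g2, frame, label,
                                    method = "RASTER") {
  if (identical(set_g1$grader, set_g2$grader))
    oc_stop("usage_error",
            "interobserver agreement needs two distinct graders (both '%s')",
            set_g1$grader)
  r1 <- get_roi(set_g1, label)
  r2 <- get_roi(set_g2, label)
  res <- jaccard_index(r1, r2, frame, method)
  res$meta <- list(eye_id = set_g1$eye_id, timepoint = set_g1$timepoint,
                   graders = c(set_g1$grader, set_g2$grader),
                   comparison = "interobserver", label = label)
  res
}

#' Cohort summary of Jaccard indices
#'
#' @param results list of `overlap_result`s (or a numeric vector of Jaccard
#'   values).
#' @return list with `mean`, `sd` (sample SD, n-1 denominator; 0 with
#'   `n1_flag = TRUE` when n = 1) and `n`.
#' @export
cohort_ji_summary <- function(results) {
  ji <- if (is.numeric(results)) results
  else vapply(results, function(r) r$jaccard, 0)
  if (!length(ji)) oc_stop("empty_input_error", "no Jaccard values given")
  list(mean = mean(ji),
       sd = if (length(ji) > 1) sd(ji) else 0,
       n = length(ji),
       n1_flag = length(ji) == 1)
}
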