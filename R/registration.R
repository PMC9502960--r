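# Landmark-based affine registration. The transform is the six-coefficient
# planar map (x, y) -> (u, v):
#   u = a00 x + a01 y + a02
#   v = a10 x + a11 y + a12
# Convention: ICGA is the moving image, the OCTA choriocapillaris slab the
# fixed frame; overlap is always computed on the fixed (OCTA) pixel grid.

#' Construct an affine transform
#'
#' @param a00,a01,a02,a10,a11,a12 coefficients of the 2x3 matrix mapping the
#'   column (x, y, 1) to (u, v).
#' @return an object of class `affine_transform`.
#' @examples
#' t <- affine_transform(1, 0, 10, 0, 1, 20)   # translation by (10, 20)
#' apply_to_point(t, c(1, 1))                  # (11, 21)
#' @export
affine_transform <- function(a00 = 1, a01 = 0, a02 = 0,
                             a10 = 0, a11 = 1, a12 = 0) {
  co <- c(a00 = a00, a01 = a01, a02 = a02, a10 = a10, a11 = a11, a12 = a12)
  if (!is_finite_num(co))
    oc_stop("configuration_error", "affine coefficients must be finite")
  structure(as.list(co), class = "affine_transform")
}

#' @export
print.affine_transform <- function(x, ...) {
  cat(sprintf("<affine> [%.6g %.6g %.6g; %.6g %.6g %.6g] det=%.6g\n",
              x$a00, x$a01, x$a02, x$a10, x$a11, x$a12, affine_det(x)))
  invisible(x)
}

#' Determinant of the linear part
#' @param t an [affine_transform].
#' @export
affine_det <- function(t) t$a00 * t$a11 - t$a01 * t$a10

#' Invert an affine transform
#' @param t an [affine_transform]; errors (`singular_transform_error`) when
#'   the linear part is singular.
#' @export
invert_affine <- function(t) {
  d <- affine_det(t)
  if (!is.finite(d) || abs(d) < 1e-12)
    oc_stop("singular_transform_error",
            "affine transform is singular (|det| = %.3g)", abs(d))
  affine_transform(t$a11 / d, -t$a01 / d,
                   (t$a01 * t$a12 - t$a11 * t$a02) / d,
                   -t$a10 / d, t$a00 / d,
                   (t$a10 * t$a02 - t$a00 * t$a12) / d)
}

#' Compose two affine transforms
#' @param t2,t1 transforms; the result applies `t1` first, then `t2`.
#' @export
compose_affine <- function(t2, t1) {
  affine_transform(t2$a00 * t1$a00 + t2$a01 * t1$a10,
                   t2$a00 * t1$a01 + t2$a01 * t1$a11,
                   t2$a00 * t1$a02 + t2$a01 * t1$a12 + t2$a02,
                   t2$a10 * t1$a00 + t2$a11 * t1$a10,
                   t2$a10 * t1$a01 + t2$a11 * t1$a11,
                   t2$a10 * t1$a02 + t2$a11 * t1$a12 + t2$a12)
}

#' Apply an affine transform to points
#'
#' @param t an [affine_transform].
#' @param p a length-2 numeric `c(x, y)`, or a matrix/data.frame with columns
#'   x, y.
#' @return same shape as the input.
#' @export
apply_to_point <- function(t, p) {
  if (is.numeric(p) && length(p) == 2 && is.null(dim(p))) {
    return(c(t$a00 * p[1] + t$a01 * p[2] + t$a02,
             t$a10 * p[1] + t$a11 * p[2] + t$a12))
  }
  x <- if (is.data.frame(p)) p$x else p[, 1]
  y <- if (is.data.frame(p)) p$y else p[, 2]
  u <- t$a00 * x + t$a01 * y + t$a02
  v <- t$a10 * x + t$a11 * y + t$a12
  if (is.data.frame(p)) data.frame(x = u, y = v) else cbind(u, v)
}

#' Estimate the affine transform from matched landmark pairs
#'
#' For exactly 3 non-collinear pairs this is the unique interpolating affine
#' (residuals at machine precision); for more pairs, the least-squares
#' minimizer of the summed squared landmark residuals. Degeneracy is declared
#' when the smallest singular value of the centered moving-point matrix falls
#' below `cond_tol` times the largest.
#'
#' @param pairs a data.frame with columns `moving_x`, `moving_y`, `fixed_x`,
#'   `fixed_y` (0-based pixel coordinates).
#' @param cond_tol collinearity threshold on the singular-value ratio.
#' @return a list of class `registration_result`: `transform`, `rmse` (px),
#'   `max_residual` (px), `n_landmarks`.
#' @export
estimate_affine <- function(pairs, cond_tol = 1e-6) {
  pairs <- as.data.frame(pairs)
  need <- c("moving_x", "moving_y", "fixed_x", "fixed_y")
  if (!all(need %in% names(pairs)))
    oc_stop("configuration_error",
            "landmark table needs columns %s", paste(need, collapse = ", "))
  n <- nrow(pairs)
  if (n < 3)
    oc_stop("insufficient_landmarks_error",
            "affine estimation needs >= 3 landmark pairs, got %d", n)
  if (!is_finite_num(unlist(pairs[need])))
    oc_stop("configuration_error", "landmark coordinates must be finite")
  M <- cbind(pairs$moving_x, pairs$moving_y)
  sv <- svd(scale(M, center = TRUE, scale = FALSE))$d
  if (sv[2] < cond_tol * sv[1])
    oc_stop("degenerate_configuration_error",
            paste0("moving landmarks are (near-)collinear: singular-value ",
                   "ratio %.3g below threshold %.3g"), sv[2] / sv[1],
            cond_tol)
  D <- cbind(M, 1)
  cu <- qr.solve(D, pairs$fixed_x)
  cv <- qr.solve(D, pairs$fixed_y)
  t <- affine_transform(cu[1], cu[2], cu[3], cv[1], cv[2], cv[3])
  pred <- apply_to_point(t, data.frame(x = M[, 1], y = M[, 2]))
  res <- sqrt((pred$x - pairs$fixed_x)^2 + (pred$y - pairs$fixed_y)^2)
  structure(list(transform = t,
                 rmse = sqrt(mean(res^2)),
                 max_residual = max(res),
                 n_landmarks = n),
            class = "registration_result")
}

#' @export
print.registration_result <- function(x, ...) {
  cat(sprintf("<registration> n=%d, rmse=%.4g px, max residual=%.4g px\n",
              x$n_landmarks, x$rmse, x$max_residual))
  print(x$transform)
  invisible(x)
}

#' Transform an ROI's polygon vertices
#'
#' ROIs are transformed as polygons (vertex mapping), never by warping masks;
#' masks are derived after transformation. Ring order, fill rule, label and
#' grader are preserved; the polygon area scales by `|det|` of the linear
#' part.
#'
#' @param t an [affine_transform].
#' @param roi a [roi].
#' @param target_frame optional [image_frame] to attach to the result.
#' @return a transformed [roi].
#' @export
apply_to_roi <- function(t, roi, target_frame = NULL) {
  stopifnot(inherits(roi, "roi"))
  rings <- lapply(roi$rings, function(r) {
    u <- t$a00 * r$x + t$a01 * r$y + t$a02
    v <- t$a10 * r$x + t$a11 * r$y + t$a12
    list(x = u, y = v)
  })
  roi(rings, label = roi$label, grader = roi$grader,
      frame = target_frame %||% roi$frame)
}

#' Warp a grayscale image through an affine transform
#'
#' Inverse warping: each target pixel center is pulled through `t^-1` and
#' sampled from the source with the chosen interpolation; samples falling
#' outside the source fill with 0.
#'
#' @param t an invertible [affine_transform] mapping source to target.
#' @param image numeric matrix (rows = y, columns = x), intensities in
#'   `[0, 1]`.
#' @param target_frame [image_frame] of the output grid.
#' @param interpolation `"bilinear"` (default for intensity images) or
#'   `"nearest"` (for masks).
#' @return numeric matrix `target_frame$height` x `target_frame$width`.
#' @export
warp_image <- function(t, image, target_frame,
                       interpolation = c("bilinear", "nearest")) {
  interpolation <- match.arg(interpolation)
  tin <- invert_affine(t)
  W <- target_frame$width; H <- target_frame$height
  gx <- rep(0:(W - 1), each = H)
  gy <- rep(0:(H - 1), times = W)
  sx <- tin$a00 * gx + tin$a01 * gy + tin$a02
  sy <- tin$a10 * gx + tin$a11 * gy + tin$a12
  sh <- nrow(image); sw <- ncol(image)
  out <- numeric(W * H)
  if (interpolation == "nearest") {
    ix <- round(sx); iy <- round(sy)
    ok <- ix >= 0 & ix <= sw - 1 & iy >= 0 & iy <= sh - 1
    out[ok] <- image[cbind(iy[ok] + 1, ix[ok] + 1)]
  } else {
    x0 <- floor(sx); y0 <- floor(sy)
    fx <- sx - x0; fy <- sy - y0
    # zero-padded source sampling
    samp <- function(ix, iy) {
      v <- numeric(length(ix))
      ok <- ix >= 0 & ix <= sw - 1 & iy >= 0 & iy <= sh - 1
      v[ok] <- image[cbind(iy[ok] + 1, ix[ok] + 1)]
      v
    }
    out <- (1 - fx) * (1 - fy) * samp(x0, y0) +
      fx * (1 - fy) * samp(x0 + 1, y0) +
      (1 - fx) * fy * samp(x0, y0 + 1) +
      fx * fy * samp(x0 + 1, y0 + 1)
  }
  matrix(out, nrow = H, ncol = W)
}

#' Read a landmark pair table
#'
#' @param path CSV with header `moving_x, moving_y, fixed_x, fixed_y`
#'   (0-based px; moving = ICGA, fixed = OCTA).
#' @return data.frame of landmark pairs.
#' @export
read_landmarks_csv <- function(path) {
  if (!file.exists(path))
    oc_stop("configuration_error", "landmark file not found: %s", path)
  lm <- read.csv(path)
  need <- c("moving_x", "moving_y", "fixed_x", "fixed_y")
  if (!all(need %in% names(lm)))
    oc_stop("configuration_error",
            "landmark CSV %s must have header %s", path,
            paste(need, collapse = ", "))
  lm
}

#' Serialize / deserialize an affine transform as JSON
#'
#' @param t an [affine_transform]; `path` a JSON file.
#' @return `read_affine_json` returns an [affine_transform].
#' @export
write_affine_json <- function(t, path) {
  jsonlite::write_json(unclass(t), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_affine_json
#' @param path JSON file with the six named coefficients.
#' @export
read_affine_json <- function(path) {
  co <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(affine_transform, as.list(co[c("a00", "a01", "a02",
                                         "a10", "a11", "a12")]))
}
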