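# Planar geometry on ROI rings: shoelace areas under the even-odd rule and
# pixel-center rasterization. Rings are implicitly closed.

# Signed shoelace area of one ring (positive = counterclockwise in a y-up
# frame; sign is irrelevant to even-odd area, which uses parity).
ring_signed_area <- function(ring) {
  x <- ring$x; y <- ring$y
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  0.5 * sum(x * yn - xn * y)
}

# Even-odd crossing-number test of points (px, py) against one ring.
# Returns logical vector; points exactly on an edge are assigned by the
# half-open crossing rule (measure-zero set, deterministic).
ring_crossings <- function(ring, px, py) {
  x1 <- ring$x; y1 <- ring$y
  x2 <- c(x1[-1], x1[1]); y2 <- c(y1[-1], y1[1])
  inside <- rep(FALSE, length(px))
  for (e in seq_along(x1)) {
    straddles <- (y1[e] > py) != (y2[e] > py)
    if (any(straddles)) {
      xi <- (x2[e] - x1[e]) * (py[straddles] - y1[e]) /
        (y2[e] - y1[e]) + x1[e]
      hit <- px[straddles] < xi
      inside[straddles] <- xor(inside[straddles], hit)
    }
  }
  inside
}

# Even-odd membership of points against all rings of an ROI.
points_in_roi <- function(roi, px, py) {
  inside <- rep(FALSE, length(px))
  for (ring in roi$rings) inside <- xor(inside, ring_crossings(ring, px, py))
  inside
}

#' Polygon area of an ROI in px^2
#'
#' Even-odd area. For a single ring this is the absolute shoelace area; for
#' non-touching rings each contributes its absolute shoelace area with sign
#' `(-1)^depth` (depth = number of other rings containing it), so holes are
#' subtracted and islands inside holes added back — exact arithmetic. When
#' ring bounding boxes overlap (nested or potentially crossing rings) the
#' even-odd fill is first resolved by polygon simplification.
#'
#' @param roi a [roi].
#' @return area in px^2, >= 0.
#' @export
polygon_area_px <- function(roi) {
  stopifnot(inherits(roi, "roi"))
  n <- length(roi$rings)
  if (n == 1) return(abs(ring_signed_area(roi$rings[[1]])))
  bb <- lapply(roi$rings, function(r)
    c(min(r$x), max(r$x), min(r$y), max(r$y)))
  touching <- FALSE
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (bb[[i]][1] <= bb[[j]][2] && bb[[j]][1] <= bb[[i]][2] &&
        bb[[i]][3] <= bb[[j]][4] && bb[[j]][3] <= bb[[i]][4]) {
      touching <- TRUE
    }
  }
  if (!touching)
    return(sum(vapply(roi$rings, function(r) abs(ring_signed_area(r)), 0)))
  simp <- polyclip::polysimplify(roi$rings, filltype = "evenodd")
  if (!length(simp)) return(0)
  max(sum(vapply(simp, ring_signed_area, 0)) * area_orientation(simp), 0)
}

# polysimplify returns outers and holes with opposite orientations; make the
# net signed sum positive by orienting on the largest ring.
area_orientation <- function(rings) {
  a <- vapply(rings, ring_signed_area, 0)
  if (sign(a[which.max(abs(a))]) >= 0) 1 else -1
}

#' Construct a binary mask
#'
#' @param grid logical matrix, rows = y (height), columns = x (width).
#' @param frame the [image_frame] the grid realizes.
#' @return an object of class `binary_mask`.
#' @export
binary_mask <- function(grid, frame) {
  stopifnot(inherits(frame, "image_frame"), is.logical(grid))
  if (nrow(grid) != frame$height || ncol(grid) != frame$width)
    oc_stop("shape_error",
            "mask grid %dx%d does not match frame %dx%d",
            nrow(grid), ncol(grid), frame$height, frame$width)
  structure(list(grid = grid, frame = frame), class = "binary_mask")
}

#' @rdname binary_mask
#' @param mask a `binary_mask`.
#' @return `mask_area_px`: number of true cells.
#' @export
mask_area_px <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  sum(mask$grid)
}

#' Rasterize an ROI onto a frame's pixel grid
#'
#' Cell (i, j) (0-based row i, column j) is true iff the pixel center at
#' continuous coordinates (x = j, y = i) lies inside the even-odd fill of the
#' ROI's rings. Deterministic; restricted to the ring bounding box for speed.
#'
#' @param roi a [roi].
#' @param frame target [image_frame].
#' @return a [binary_mask].
#' @export
roi_to_mask <- function(roi, frame) {
  stopifnot(inherits(roi, "roi"), inherits(frame, "image_frame"))
  W <- frame$width; H <- frame$height
  grid <- matrix(FALSE, nrow = H, ncol = W)
  xs <- unlist(lapply(roi$rings, `[[`, "x"))
  ys <- unlist(lapply(roi$rings, `[[`, "y"))
  j0 <- max(0L, floor(min(xs))); j1 <- min(W - 1L, ceiling(max(xs)))
  i0 <- max(0L, floor(min(ys))); i1 <- min(H - 1L, ceiling(max(ys)))
  if (j0 > j1 || i0 > i1) return(binary_mask(grid, frame))
  jj <- j0:j1; ii <- i0:i1
  px <- rep(jj, times = length(ii))
  py <- rep(ii, each = length(jj))
  inside <- points_in_roi(roi, px, py)
  sub <- matrix(inside, nrow = length(jj), ncol = length(ii))
  grid[ii + 1L, jj + 1L] <- t(sub)
  binary_mask(grid, frame)
}
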