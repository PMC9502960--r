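# Shared fixtures and independent oracles for the test suite.

sq_roi <- function(x0, y0, side, label = NULL, grader = NULL) {
  roi(list(x = c(x0, x0 + side, x0 + side, x0),
           y = c(y0, y0, y0 + side, y0 + side)),
      label = label, grader = grader)
}

# random simple star-shaped polygon around (cx, cy): jittered equal angular
# spacing keeps every gap well under pi, so the ring cannot self-intersect
random_star_poly <- function(cx = 50, cy = 50, rmin = 10, rmax = 30,
                             nmin = 5, nmax = 14) {
  n <- sample(nmin:nmax, 1)
  th <- (seq_len(n) - 1 + runif(n, 0.05, 0.95)) / n * 2 * pi
  r <- runif(n, rmin, rmax)
  roi(list(x = cx + r * cos(th), y = cy + r * sin(th)))
}

ring_perimeter <- function(ring) {
  dx <- diff(c(ring$x, ring$x[1])); dy <- diff(c(ring$y, ring$y[1]))
  sum(sqrt(dx^2 + dy^2))
}

roi_perimeter <- function(r) sum(vapply(r$rings, ring_perimeter, 0))

# Independent even-odd point-in-polygon oracle built on sp::point.in.polygon
# (parity over rings; boundary counted as inside by sp, irrelevant off-grid).
oracle_points_in_roi <- function(roi, px, py) {
  inside <- rep(FALSE, length(px))
  for (ring in roi$rings) {
    hit <- sp::point.in.polygon(px, py, ring$x, ring$y) > 0
    inside <- xor(inside, hit)
  }
  inside
}

# Supersampled raster area oracle (cells per px = ss) on the ROI bbox.
oracle_raster_area <- function(roi, ss = 8) {
  xs <- unlist(lapply(roi$rings, `[[`, "x"))
  ys <- unlist(lapply(roi$rings, `[[`, "y"))
  gx <- seq(floor(min(xs)) - 1, ceiling(max(xs)) + 1, by = 1 / ss)
  gy <- seq(floor(min(ys)) - 1, ceiling(max(ys)) + 1, by = 1 / ss)
  px <- rep(gx, times = length(gy))
  py <- rep(gy, each = length(gx))
  sum(oracle_points_in_roi(roi, px, py)) / ss^2
}

# Exact two-sided signed-rank p-value by full enumeration of sign vectors.
enumerate_signrank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  W_all <- signs %*% r
  p_le <- mean(W_all <= W_obs)
  p_ge <- mean(W_all >= W_obs)
  min(1, 2 * min(p_le, p_ge))
}
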