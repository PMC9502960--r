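# Ground-truthed synthetic paired-modality scenes. A scene holds the true
# lesion polygons on the OCTA frame (type A hyper-reflective area, type B
# halo annulus, type C spots inside A), their ICGA counterparts
# (hyperfluorescence = affine image of type A with a boundary discrepancy;
# hypofluorescence = shrunken type C spots), landmark pairs related exactly
# by the true affine, and rendered images. Every stage of the pipeline is
# testable against this ground truth.

#' Scene generator parameters
#'
#' Defaults describe the emulated study conditions: a 1024 x 1024 px frame
#' over a 12 x 12 mm field, three landmarks, a random inter-modality affine
#' within rotation +/-10 degrees, scale 0.9-1.1 and translation +/-30 px, a
#' type A lesion of mean radius 1.5 mm with a star-convex boundary
#' r(theta) = r0 (1 + sum_k a_k cos(k theta + phi_k)), a halo present with
#' probability 0.821, and three type C spots. The boundary-noise defaults
#' (cross-modality discrepancy 45 px, grader noise 18 px) are set so the
#' synthetic cohort reproduces the magnitude of agreement reported for this
#' kind of data: moderate cross-modality concordance (Jaccard near 0.5-0.6)
#' and high interobserver agreement (near 0.7-0.8).
#'
#' @param seed master seed; fixes the whole scene deterministically.
#' @param frame OCTA [image_frame] (ICGA uses the same dimensions).
#' @param n_landmarks number of landmark pairs (>= 3).
#' @param true_affine optional [affine_transform] mapping ICGA (moving) to
#'   OCTA (fixed); when `NULL` one is drawn within the stated ranges.
#' @param typeA_radius_mm,typeA_radius_jitter_mm mean and SD of the type A
#'   base radius.
#' @param typeA_harmonics,typeA_harmonic_amp count and amplitude scale of
#'   the radial Fourier perturbation (amplitudes bounded so r > 0).
#' @param halo_present probability that the type B halo exists.
#' @param halo_width_mm radial width of the halo annulus.
#' @param n_typeC_spots,spot_radius_mm count and mean radius of type C
#'   spots (strictly inside type A).
#' @param hypo_shrink radius factor (< 1) of hypofluorescent spots relative
#'   to their type C counterparts.
#' @param icga_boundary_sigma_px boundary discrepancy (px) between the
#'   hyperfluorescence region and the affine image of type A.
#' @param grader_sigma_px default boundary noise of simulated graders.
#' @param noise_level multiplicative speckle amplitude of the renderer.
#' @param contrast mean intensity elevation inside type A over background.
#' @return list of class `scene_params`.
#' @export
scene_params <- function(seed = 1L,
                         frame = image_frame(1024, 1024, 12, 12),
                         n_landmarks = 3L,
                         true_affine = NULL,
                         typeA_radius_mm = 1.5,
                         typeA_radius_jitter_mm = 0.2,
                         typeA_harmonics = 4L,
                         typeA_harmonic_amp = 0.06,
                         halo_present = 0.821,
                         halo_width_mm = 0.4,
                         n_typeC_spots = 3L,
                         spot_radius_mm = 0.18,
                         hypo_shrink = 0.7,
                         icga_boundary_sigma_px = 45,
                         grader_sigma_px = 18,
                         noise_level = 0.15,
                         contrast = 0.4) {
  if (n_landmarks < 3)
    oc_stop("configuration_error", "at least 3 landmarks are required")
  if (halo_present < 0 || halo_present > 1)
    oc_stop("configuration_error", "halo_present must be a probability")
  if (any(c(typeA_radius_mm, halo_width_mm, spot_radius_mm) <= 0))
    oc_stop("configuration_error", "physical sizes must be positive")
  if (spot_radius_mm >= typeA_radius_mm * (1 - typeA_harmonic_amp *
                                           max(1, typeA_harmonics) * 0.5))
    oc_stop("configuration_error",
            "spot radius %.3g mm does not fit inside a type A lesion of %.3g mm",
            spot_radius_mm, typeA_radius_mm)
  if (icga_boundary_sigma_px < 0 || grader_sigma_px < 0 || noise_level < 0)
    oc_stop("configuration_error", "noise scales must be >= 0")
  if (hypo_shrink <= 0 || hypo_shrink >= 1)
    oc_stop("configuration_error", "hypo_shrink must be in (0, 1)")
  structure(as.list(environment()), class = "scene_params")
}

# Smooth angularly-correlated unit-variance Gaussian noise sampled at
# angles th (radians): a random finite Fourier series whose Gaussian
# spectrum w_k = exp(-(k s)^2 / 2) corresponds to an angular correlation
# length s. The k = 0 term gives each realization a radial (size) bias,
# like a grader's systematic over/under-segmentation.
smooth_circular_noise <- function(th, corr_deg = 30) {
  s <- corr_deg * pi / 180
  K <- max(3L, ceiling(4 / s))
  k <- seq_len(K)
  w <- exp(-0.5 * (k * s)^2)
  a0 <- rnorm(1); a <- rnorm(K); b <- rnorm(K)
  z <- a0 + cos(outer(th, k)) %*% (w * a) + sin(outer(th, k)) %*% (w * b)
  as.vector(z) / sqrt(1 + sum(w^2))
}

star_ring <- function(cx, cy, r0, amps = numeric(), phases = numeric(),
                      ks = integer(), n = 256L, r_extra = 0) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  per <- rep(0, n)
  for (i in seq_along(amps))
    per <- per + amps[i] * cos(ks[i] * th + phases[i])
  r <- r0 * (1 + per) + r_extra
  list(x = cx + r * cos(th), y = cy + r * sin(th))
}

#' Circular-disc ROI
#'
#' @param cx,cy center (px); `r` radius (px); `n` vertex count.
#' @param label,grader passed to [roi()].
#' @return a polygonal [roi] approximating the disc.
#' @export
disc_roi <- function(cx, cy, r, n = 256L, label = NULL, grader = NULL) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  roi(list(x = cx + r * cos(th), y = cy + r * sin(th)),
      label = label, grader = grader)
}

#' Closed-form intersection area of two discs
#'
#' Lens area of discs with radii `r1`, `r2` at center distance `d`; the
#' analytic oracle for overlap tests.
#' @param r1,r2 radii; `d` center distance (same units).
#' @return intersection area.
#' @export
circle_overlap_area <- function(r1, r2, d) {
  if (d >= r1 + r2) return(0)
  if (d <= abs(r1 - r2)) return(pi * min(r1, r2)^2)
  a1 <- r1^2 * acos((d^2 + r1^2 - r2^2) / (2 * d * r1))
  a2 <- r2^2 * acos((d^2 + r2^2 - r1^2) / (2 * d * r2))
  tri <- 0.5 * sqrt((-d + r1 + r2) * (d + r1 - r2) *
                    (d - r1 + r2) * (d + r1 + r2))
  a1 + a2 - tri
}

random_affine_in_ranges <- function(cx, cy) {
  ang <- runif(1, -10, 10) * pi / 180
  s <- runif(1, 0.9, 1.1)
  tx <- runif(1, -30, 30); ty <- runif(1, -30, 30)
  lin <- s * matrix(c(cos(ang), -sin(ang), sin(ang), cos(ang)),
                    2, byrow = TRUE)
  # rotate/scale about the frame center, then translate
  off <- c(cx, cy) - lin %*% c(cx, cy) + c(tx, ty)
  affine_transform(lin[1, 1], lin[1, 2], off[1],
                   lin[2, 1], lin[2, 2], off[2])
}

# Perturb a ring radially about its vertex centroid with smooth circular
# noise of SD sigma px; clipped so the radius stays positive.
perturb_ring <- function(ring, sigma, corr_deg = 30) {
  if (sigma == 0) return(ring)
  cx <- mean(ring$x); cy <- mean(ring$y)
  dx <- ring$x - cx; dy <- ring$y - cy
  r <- sqrt(dx^2 + dy^2)
  th <- atan2(dy, dx)
  rn <- pmax(r + sigma * smooth_circular_noise(th, corr_deg), 0.1 * median(r))
  list(x = cx + rn * cos(th), y = cy + rn * sin(th))
}

#' Generate one ground-truthed paired-modality scene
#'
#' Deterministic in `params$seed`. Invariants guaranteed by construction:
#' type C spots lie strictly inside type A; the type B annulus borders type
#' A with disjoint interior; every OCTA landmark equals the true affine
#' applied to its ICGA counterpart exactly; hypofluorescent spots are
#' strictly smaller than their type C counterparts mapped to the ICGA frame.
#'
#' @param params a [scene_params].
#' @return list of class `gt_scene` with elements `params`, `octa_frame`,
#'   `icga_frame`, `true_affine` (ICGA -> OCTA), `octa_truth` and
#'   `icga_truth` ([annotation_set]s, grader `"truth"`), `landmarks`
#'   (moving = ICGA, fixed = OCTA), `center` (type A center, px), and
#'   `analytic_mm2` (closed-form areas where available).
#' @export
generate_scene <- function(params = scene_params()) {
  stopifnot(inherits(params, "scene_params"))
  fr <- params$frame
  icga_frame <- image_frame(fr$width, fr$height, fr$fov_width,
                            fr$fov_height, "ICGA_MID")
  px_per_mm <- fr$width / fr$fov_width
  with_seed(child_seed(params$seed, 17L), {
    taff <- params$true_affine %||%
      random_affine_in_ranges((fr$width - 1) / 2, (fr$height - 1) / 2)
    tinv <- invert_affine(taff)

    cx <- (fr$width - 1) / 2 + runif(1, -40, 40)
    cy <- (fr$height - 1) / 2 + runif(1, -40, 40)
    r0 <- max(0.3, rnorm(1, params$typeA_radius_mm,
                         params$typeA_radius_jitter_mm)) * px_per_mm
    nh <- params$typeA_harmonics
    amps <- phases <- numeric(0); ks <- integer(0)
    if (nh > 0 && params$typeA_harmonic_amp > 0) {
      ks <- 2:(nh + 1)
      amps <- params$typeA_harmonic_amp * runif(nh, 0.3, 1) / sqrt(ks - 1)
      if (sum(amps) > 0.45) amps <- amps * 0.45 / sum(amps)
      phases <- runif(nh, 0, 2 * pi)
    }
    ringA <- star_ring(cx, cy, r0, amps, phases, ks)
    roiA <- roi(ringA, label = "TYPE_A", grader = "truth", frame = fr)

    halo <- runif(1) < params$halo_present
    roiB <- NULL
    if (halo) {
      wpx <- params$halo_width_mm * px_per_mm
      outer <- star_ring(cx, cy, r0, amps, phases, ks, r_extra = wpx)
      roiB <- roi(list(outer, ringA), label = "TYPE_B", grader = "truth",
                  frame = fr)
    }

    r_min <- r0 * (1 - if (length(amps)) sum(amps) else 0)
    spot_r_px <- params$spot_radius_mm * px_per_mm
    spots <- list()
    spot_geom <- list()
    tries <- 0
    while (length(spots) < params$n_typeC_spots && tries < 400) {
      tries <- tries + 1
      sr <- spot_r_px * runif(1, 0.8, 1.2)
      ang <- runif(1, 0, 2 * pi)
      dmax <- 0.85 * r_min - sr
      if (dmax <= 0)
        oc_stop("configuration_error",
                "spot radius too large for the lesion interior")
      dd <- sqrt(runif(1)) * dmax
      sx <- cx + dd * cos(ang); sy <- cy + dd * sin(ang)
      clear <- all(vapply(spot_geom, function(g)
        sqrt((g$x - sx)^2 + (g$y - sy)^2) > g$r + sr + 2, TRUE))
      if (clear) {
        spot_geom[[length(spot_geom) + 1]] <- list(x = sx, y = sy, r = sr)
        th <- seq(0, 2 * pi, length.out = 65)[-65]
        spots[[length(spots) + 1]] <- list(x = sx + sr * cos(th),
                                           y = sy + sr * sin(th))
      }
    }
    roiC <- if (length(spots))
      roi(spots, label = "TYPE_C", grader = "truth", frame = fr) else NULL

    # ICGA truth: hyperfluorescence = affine^-1(type A) with boundary
    # discrepancy; hypofluorescence = shrunken type C spots, mapped over.
    hyper0 <- apply_to_roi(tinv, roiA, icga_frame)
    hyper_rings <- lapply(hyper0$rings, perturb_ring,
                          sigma = params$icga_boundary_sigma_px)
    roiH <- roi(hyper_rings, label = "HYPERFLUORESCENCE", grader = "truth",
                frame = icga_frame)
    roiHypo <- NULL
    if (length(spot_geom)) {
      shr <- lapply(seq_along(spots), function(i) {
        g <- spot_geom[[i]]
        list(x = g$x + (spots[[i]]$x - g$x) * params$hypo_shrink,
             y = g$y + (spots[[i]]$y - g$y) * params$hypo_shrink)
      })
      roiHypo <- apply_to_roi(tinv, roi(shr), icga_frame)
      roiHypo$label <- "HYPOFLUORESCENCE"; roiHypo$grader <- "truth"
    }

    # landmarks on the fixed (OCTA) frame: spread, pairwise >= 200 px apart
    # and non-collinear by construction; ICGA counterparts are exact affine
    # preimages.
    base_lm <- rbind(c(0.20, 0.20), c(0.80, 0.30), c(0.35, 0.80))
    fx <- base_lm[, 1] * (fr$width - 1) + runif(3, -20, 20)
    fy <- base_lm[, 2] * (fr$height - 1) + runif(3, -20, 20)
    extra <- params$n_landmarks - 3L
    while (extra > 0) {
      px <- runif(1, 0.1, 0.9) * (fr$width - 1)
      py <- runif(1, 0.1, 0.9) * (fr$height - 1)
      if (all(sqrt((fx - px)^2 + (fy - py)^2) > 100)) {
        fx <- c(fx, px); fy <- c(fy, py); extra <- extra - 1L
      }
    }
    mv <- apply_to_point(tinv, data.frame(x = fx, y = fy))
    landmarks <- data.frame(moving_x = mv$x, moving_y = mv$y,
                            fixed_x = fx, fixed_y = fy)

    s_mm2 <- px_area_mm2(fr)
    analytic <- list(
      typeA = if (!length(amps)) pi * r0^2 * s_mm2 else NA_real_,
      typeC = if (length(spot_geom))
        sum(vapply(spot_geom, function(g) pi * g$r^2, 0)) * s_mm2
      else NA_real_)

    octa_rois <- Filter(Negate(is.null), list(roiA, roiB, roiC))
    icga_rois <- Filter(Negate(is.null), list(roiH, roiHypo))
    structure(list(params = params, octa_frame = fr,
                   icga_frame = icga_frame,
                   true_affine = taff,
                   octa_truth = annotation_set("synthetic", 0L,
                                               grader = "truth",
                                               rois = octa_rois),
                   icga_truth = annotation_set("synthetic", 0L,
                                               grader = "truth",
                                               rois = icga_rois),
                   landmarks = landmarks,
                   center = c(cx, cy),
                   analytic_mm2 = analytic),
              class = "gt_scene")
  })
}

#' @export
print.gt_scene <- function(x, ...) {
  cat(sprintf("<gt_scene> seed=%d, %d OCTA + %d ICGA truth ROIs, %d landmarks\n",
              x$params$seed, length(x$octa_truth$rois),
              length(x$icga_truth$rois), nrow(x$landmarks)))
  invisible(x)
}

# separable Gaussian blur with edge replication
blur_gaussian <- function(img, sigma) {
  if (sigma <= 0) return(img)
  half <- ceiling(3 * sigma)
  k <- exp(-0.5 * ((-half:half) / sigma)^2); k <- k / sum(k)
  pad_idx <- function(i, n) pmin(pmax(i, 1L), n)
  H <- nrow(img); W <- ncol(img)
  tmp <- matrix(0, H, W)
  for (d in -half:half)
    tmp <- tmp + k[d + half + 1] * img[, pad_idx(seq_len(W) + d, W)]
  out <- matrix(0, H, W)
  for (d in -half:half)
    out <- out + k[d + half + 1] * tmp[pad_idx(seq_len(H) + d, H), ]
  out
}

draw_cross <- function(img, cx, cy, arm = 8, halfw = 1, value = 1) {
  H <- nrow(img); W <- ncol(img)
  j <- max(0, floor(cx - arm - 1)):min(W - 1, ceiling(cx + arm + 1))
  i <- max(0, floor(cy - arm - 1)):min(H - 1, ceiling(cy + arm + 1))
  ov <- function(c0, c1, lo) pmin(c1, lo + 0.5) - pmax(c0, lo - 0.5)
  covx_arm <- pmax(ov(cx - arm, cx + arm, j), 0)
  covx_w <- pmax(ov(cx - halfw, cx + halfw, j), 0)
  covy_arm <- pmax(ov(cy - arm, cy + arm, i), 0)
  covy_w <- pmax(ov(cy - halfw, cy + halfw, i), 0)
  horiz <- outer(covy_w, covx_arm)          # rows = y
  vert <- outer(covy_arm, covx_w)
  cov <- pmin(horiz + vert, 1)
  sub <- img[i + 1, j + 1, drop = FALSE]
  img[i + 1, j + 1] <- sub + (value - sub) * cov
  img
}

#' Render the paired grayscale images of a scene
#'
#' OCTA: elevated mean inside type A, suppressed inside the type B halo and
#' type C spots, granular multiplicative speckle. ICGA: Gaussian-blurred
#' bright hyperfluorescence, dark hypofluorescent spots. Landmarks are drawn
#' as anti-aliased bright crosses on both images. Geometry comes from the
#' scene (shape stream); the speckle has its own stream, so different
#' `noise_seed`s change the noise but never the ground truth.
#'
#' @param scene a `gt_scene`.
#' @param noise_seed seed of the noise stream (default derived from the
#'   scene seed).
#' @param noise_level overrides `params$noise_level` when not `NULL`.
#' @return list with matrices `octa` and `icga` in `[0, 1]`.
#' @export
render_images <- function(scene, noise_seed = NULL, noise_level = NULL) {
  stopifnot(inherits(scene, "gt_scene"))
  p <- scene$params
  nl <- noise_level %||% p$noise_level
  fr <- scene$octa_frame
  bg <- 0.35
  octa <- matrix(bg, fr$height, fr$width)
  mA <- roi_to_mask(get_roi(scene$octa_truth, "TYPE_A"), fr)$grid
  octa[mA] <- bg + p$contrast
  rB <- get_roi(scene$octa_truth, "TYPE_B", required = FALSE)
  if (!is.null(rB)) octa[roi_to_mask(rB, fr)$grid] <- 0.15
  rC <- get_roi(scene$octa_truth, "TYPE_C", required = FALSE)
  if (!is.null(rC)) octa[roi_to_mask(rC, fr)$grid] <- 0.15
  octa <- blur_gaussian(octa, 1.2)

  ifr <- scene$icga_frame
  icga <- matrix(0.3, ifr$height, ifr$width)
  icga[roi_to_mask(get_roi(scene$icga_truth, "HYPERFLUORESCENCE"),
                   ifr)$grid] <- 0.3 + p$contrast
  rHy <- get_roi(scene$icga_truth, "HYPOFLUORESCENCE", required = FALSE)
  if (!is.null(rHy)) icga[roi_to_mask(rHy, ifr)$grid] <- 0.12
  icga <- blur_gaussian(icga, 2.5)

  if (nl > 0) {
    with_seed(noise_seed %||% child_seed(p$seed, 101L), {
      sp <- blur_gaussian(matrix(rnorm(length(octa)), nrow(octa)), 1)
      octa <- octa * (1 + nl * sp / sd(sp))
      gn <- blur_gaussian(matrix(rnorm(length(icga)), nrow(icga)), 1)
      icga <- icga * (1 + 0.5 * nl * gn / sd(gn))
    })
  }
  for (k in seq_len(nrow(scene$landmarks))) {
    octa <- draw_cross(octa, scene$landmarks$fixed_x[k],
                       scene$landmarks$fixed_y[k])
    icga <- draw_cross(icga, scene$landmarks$moving_x[k],
                       scene$landmarks$moving_y[k])
  }
  list(octa = pmin(pmax(octa, 0), 1), icga = pmin(pmax(icga, 0), 1))
}

#' Recover landmark positions from a rendered image
#'
#' Intensity-weighted centroid of the above-threshold pixels in a window
#' around each approximate position.
#'
#' @param image rendered grayscale matrix.
#' @param approx data.frame/matrix of approximate `x`, `y` positions.
#' @param halfwin window half-size in px.
#' @return data.frame with refined `x`, `y`.
#' @export
detect_landmarks <- function(image, approx, halfwin = 12L) {
  approx <- as.data.frame(approx)
  if (is.null(approx$x)) names(approx)[1:2] <- c("x", "y")
  out <- lapply(seq_len(nrow(approx)), function(k) {
    jx <- max(0, round(approx$x[k]) - halfwin):
      min(ncol(image) - 1, round(approx$x[k]) + halfwin)
    iy <- max(0, round(approx$y[k]) - halfwin):
      min(nrow(image) - 1, round(approx$y[k]) + halfwin)
    win <- image[iy + 1, jx + 1, drop = FALSE]
    thr <- min(win) + 0.6 * (max(win) - min(win))
    w <- pmax(win - thr, 0)
    gx <- matrix(jx, nrow(win), ncol(win), byrow = TRUE)
    gy <- matrix(iy, nrow(win), ncol(win))
    data.frame(x = sum(w * gx) / sum(w), y = sum(w * gy) / sum(w))
  })
  do.call(rbind, out)
}

#' Simulate a grader's annotation of a true region
#'
#' Radial boundary perturbation with smooth, angularly-correlated Gaussian
#' noise (default correlation length 30 degrees), applied per ring about its
#' centroid and clipped to keep a simple polygon. The effective sigma of a
#' ring is capped at 30 percent of its median radius: tracing error grows
#' with lesion size but stays proportionate on small sharp spots.
#' `sigma_px = 0` returns the truth exactly.
#'
#' @param true_roi the ground-truth [roi].
#' @param sigma_px boundary noise SD in px (>= 0).
#' @param seed RNG seed for this annotation.
#' @param grader grader identifier stamped on the result.
#' @param corr_deg angular correlation length of the boundary noise.
#' @return a perturbed [roi].
#' @export
simulate_grader <- function(true_roi, sigma_px, seed, grader = "g1",
                            corr_deg = 30) {
  stopifnot(inherits(true_roi, "roi"))
  if (sigma_px < 0)
    oc_stop("configuration_error", "grader sigma must be >= 0")
  out <- true_roi
  out$grader <- grader
  if (sigma_px == 0) return(out)
  out$rings <- with_seed(seed, lapply(true_roi$rings, function(ring) {
    r <- sqrt((ring$x - mean(ring$x))^2 + (ring$y - mean(ring$y))^2)
    perturb_ring(ring, sigma = min(sigma_px, 0.3 * median(r)),
                 corr_deg = corr_deg)
  }))
  out
}

#' Generate a longitudinal two-group cohort of scenes
#'
#' Each eye gets a baseline scene and a follow-up scene whose lesions are
#' the baseline lesions rescaled about the type A center by the group's
#' radius shrinkage factor (areas scale by the factor squared; ICGA regions
#' are rescaled through the conjugated affine so cross-modality
#' correspondence is preserved exactly). Two simulated graders annotate
#' every lesion at both visits. Groups are assigned by shuffled alternation
#' (near-balanced, like the emulated 19/20 split).
#'
#' @param n_eyes number of eyes (>= 2).
#' @param seed master cohort seed.
#' @param base_params a [scene_params] used as the per-eye template (each
#'   eye gets its own derived seed).
#' @param shrink_laser,shrink_observation radius shrinkage factors of the
#'   two arms at follow-up.
#' @param grader_sigmas boundary noise (px) of the two simulated graders.
#' @return list of class `cohort` with `eyes` (per-eye list: `eye_id`,
#'   `group`, `months`, `baseline`, `followup` scenes, `annotations`) and a
#'   `manifest` data.frame.
#' @export
generate_cohort <- function(n_eyes = 39L, seed = 1L,
                            base_params = scene_params(),
                            shrink_laser = 0.7,
                            shrink_observation = 0.7,
                            grader_sigmas = c(g1 = 18, g2 = 18)) {
  if (n_eyes < 2)
    oc_stop("configuration_error", "a cohort needs >= 2 eyes")
  groups <- with_seed(child_seed(seed, 7L),
                      sample(rep(c("OBSERVATION", "LASER"),
                                 length.out = n_eyes)))
  months_all <- with_seed(child_seed(seed, 8L),
                          sample(1:3, n_eyes, replace = TRUE))
  eyes <- vector("list", n_eyes)
  manifest <- list()
  for (i in seq_len(n_eyes)) {
    eye_id <- sprintf("eye%03d", i)
    p <- base_params
    p$seed <- child_seed(seed, 100L + i)
    base <- generate_scene(p)
    shrink <- if (groups[i] == "LASER") shrink_laser else shrink_observation
    foll <- rescale_scene(base, shrink)
    ann <- list()
    for (tp in c(0L, 1L)) {
      sc <- if (tp == 0L) base else foll
      for (g in names(grader_sigmas)) {
        gseed <- child_seed(seed, 10000L + 97L * i + 13L * tp +
                              match(g, names(grader_sigmas)))
        octa_rois <- lapply(sc$octa_truth$rois, function(r)
          simulate_grader(r, grader_sigmas[[g]],
                          child_seed(gseed, match(r$label, LESION_TYPES)),
                          grader = g))
        icga_rois <- lapply(sc$icga_truth$rois, function(r)
          simulate_grader(r, grader_sigmas[[g]],
                          child_seed(gseed, 10L + match(r$label,
                                                        LESION_TYPES)),
                          grader = g))
        ann[[sprintf("t%d_%s_octa", tp, g)]] <-
          annotation_set(eye_id, tp, groups[i], g, octa_rois)
        ann[[sprintf("t%d_%s_icga", tp, g)]] <-
          annotation_set(eye_id, tp, groups[i], g, icga_rois)
      }
    }
    eyes[[i]] <- list(eye_id = eye_id, group = groups[i],
                      months = months_all[i], baseline = base,
                      followup = foll, annotations = ann)
    manifest[[i]] <- data.frame(eye_id = eye_id, group = groups[i],
                                followup_months = months_all[i],
                                seed = p$seed, shrink = shrink,
                                stringsAsFactors = FALSE)
  }
  structure(list(eyes = eyes, manifest = do.call(rbind, manifest),
                 seed = seed),
            class = "cohort")
}

# Rescale all lesions of a scene about the type A center by a radius factor;
# ICGA regions are rescaled through the conjugated map
# affine^-1 o scale_c o affine so correspondence is preserved exactly.
rescale_scene <- function(scene, factor) {
  c0 <- scene$center
  sc_fixed <- affine_transform(factor, 0, c0[1] * (1 - factor),
                               0, factor, c0[2] * (1 - factor))
  tinv <- invert_affine(scene$true_affine)
  sc_moving <- compose_affine(tinv,
                              compose_affine(sc_fixed, scene$true_affine))
  out <- scene
  out$octa_truth$rois <- lapply(scene$octa_truth$rois, function(r)
    apply_to_roi(sc_fixed, r, scene$octa_frame))
  out$icga_truth$rois <- lapply(scene$icga_truth$rois, function(r)
    apply_to_roi(sc_moving, r, scene$icga_frame))
  out$octa_truth$timepoint <- scene$octa_truth$timepoint + 1L
  out$icga_truth$timepoint <- scene$icga_truth$timepoint + 1L
  out
}
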