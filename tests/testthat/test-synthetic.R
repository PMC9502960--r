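small_params <- function(seed, ...) {
  scene_params(seed = seed, frame = image_frame(512, 512, 12, 12), ...)
}

test_that("scenes are deterministic in the seed", {
  s1 <- generate_scene(small_params(99))
  s2 <- generate_scene(small_params(99))
  expect_equal(s1$octa_truth, s2$octa_truth)
  expect_equal(s1$landmarks, s2$landmarks)
  expect_equal(unlist(s1$true_affine), unlist(s2$true_affine))
  m1 <- roi_to_mask(get_roi(s1$octa_truth, "TYPE_A"), s1$octa_frame)
  m2 <- roi_to_mask(get_roi(s2$octa_truth, "TYPE_A"), s2$octa_frame)
  expect_identical(m1$grid, m2$grid)
  s3 <- generate_scene(small_params(100))
  expect_false(identical(s1$landmarks, s3$landmarks))
})

test_that("degenerate halo probabilities are honored", {
  none <- vapply(1:20, function(s)
    is.null(get_roi(generate_scene(small_params(s, halo_present = 0))$octa_truth,
                    "TYPE_B", required = FALSE)), TRUE)
  expect_true(all(none))
  all_h <- vapply(21:40, function(s)
    !is.null(get_roi(generate_scene(small_params(s, halo_present = 1))$octa_truth,
                     "TYPE_B", required = FALSE)), TRUE)
  expect_true(all(all_h))
})

test_that("zero harmonics give a disc whose area matches the closed form", {
  sc <- generate_scene(small_params(7, typeA_harmonic_amp = 0,
                                    typeA_radius_jitter_mm = 0))
  a <- polygon_area_px(get_roi(sc$octa_truth, "TYPE_A")) *
    px_area_mm2(sc$octa_frame)
  expect_equal(a, pi * 1.5^2, tolerance = 0.01 * pi * 1.5^2)
  expect_equal(sc$analytic_mm2$typeA, pi * 1.5^2, tolerance = 1e-9)
})

test_that("scene geometry honors the lesion-taxonomy containment
           invariants", {
  for (s in c(3, 14, 26)) {
    sc <- generate_scene(small_params(s, halo_present = 1))
    fr <- sc$octa_frame
    mA <- roi_to_mask(get_roi(sc$octa_truth, "TYPE_A"), fr)$grid
    mB <- roi_to_mask(get_roi(sc$octa_truth, "TYPE_B"), fr)$grid
    mC <- roi_to_mask(get_roi(sc$octa_truth, "TYPE_C"), fr)$grid
    expect_true(all(mA[mC]))                  # spots strictly inside A
    expect_false(any(mB & mA))                # halo disjoint from A
    # halo borders A: dilating A by one pixel reaches the halo
    shift_or <- function(m) {
      out <- m
      out[-1, ] <- out[-1, ] | m[-nrow(m), ]
      out[, -1] <- out[, -1] | m[, -ncol(m)]
      out[-nrow(m), ] <- out[-nrow(m), ] | m[-1, ]
      out[, -ncol(m)] <- out[, -ncol(m)] | m[, -1]
      out
    }
    expect_true(any(shift_or(mA) & mB))
    # hypofluorescent spots strictly smaller than mapped type C spots
    c_on_icga <- apply_to_roi(invert_affine(sc$true_affine),
                              get_roi(sc$octa_truth, "TYPE_C"))
    hypo <- get_roi(sc$icga_truth, "HYPOFLUORESCENCE")
    expect_lt(polygon_area_px(hypo), polygon_area_px(c_on_icga))
    # landmarks related exactly by the true affine
    mapped <- apply_to_point(sc$true_affine,
                             data.frame(x = sc$landmarks$moving_x,
                                        y = sc$landmarks$moving_y))
    expect_equal(mapped$x, sc$landmarks$fixed_x, tolerance = 1e-9)
    expect_equal(mapped$y, sc$landmarks$fixed_y, tolerance = 1e-9)
  }
})

test_that("impossible spot geometry raises a configuration error", {
  expect_error(small_params(1, spot_radius_mm = 1.6),
               class = "configuration_error")
  expect_error(small_params(1, hypo_shrink = 1.2),
               class = "configuration_error")
  expect_error(small_params(1, n_landmarks = 2),
               class = "configuration_error")
})

test_that("simulated graders return the truth at sigma 0 and degrade
           monotonically", {
  truth <- disc_roi(250, 250, 120, label = "TYPE_A")
  fr <- image_frame(512, 512, 12, 12)
  g0 <- simulate_grader(truth, 0, 1, "g1")
  expect_identical(g0$rings, truth$rings)
  expect_identical(g0$grader, "g1")
  ji <- function(sigma) vapply(1:30, function(s)
    jaccard_index(truth, simulate_grader(truth, sigma, s, "g1"), fr,
                  "POLYGON")$jaccard, 0)
  j4 <- ji(4); j12 <- ji(12)
  expect_gt(mean(j4), 0.8); expect_lt(mean(j4), 1)
  expect_gt(mean(j4), mean(j12))
  expect_error(simulate_grader(truth, -1, 1), class = "configuration_error")
})

test_that("renderer separates shape and noise streams and hits the
           configured contrast", {
  sc <- generate_scene(small_params(5))
  quiet <- render_images(sc, noise_level = 0)
  # contrast: interior (eroded) mean minus background mean
  mA <- roi_to_mask(get_roi(sc$octa_truth, "TYPE_A"), sc$octa_frame)$grid
  mAll <- mA
  for (r in sc$octa_truth$rois)
    mAll <- mAll | roi_to_mask(r, sc$octa_frame)$grid
  erode <- function(m, k) {
    for (i in seq_len(k)) {
      m[-1, ] <- m[-1, ] & m[-nrow(m), ]; m[, -1] <- m[, -1] & m[, -ncol(m)]
      m[-nrow(m), ] <- m[-nrow(m), ] & m[-1, ]
      m[, -ncol(m)] <- m[, -ncol(m)] & m[, -1]
    }
    m
  }
  dilate <- function(m, k) !erode(!m, k)
  core <- erode(mA, 8)
  # mask out type B/C and landmark neighborhoods from core and background
  for (lab in c("TYPE_B", "TYPE_C")) {
    rr <- get_roi(sc$octa_truth, lab, required = FALSE)
    if (!is.null(rr))
      core <- core & !dilate(roi_to_mask(rr, sc$octa_frame)$grid, 8)
  }
  bg <- !dilate(mAll, 8)
  for (k in seq_len(nrow(sc$landmarks))) {
    jx <- pmax(1, pmin(512, round(sc$landmarks$fixed_x[k]) + (-12:12)))
    iy <- pmax(1, pmin(512, round(sc$landmarks$fixed_y[k]) + (-12:12)))
    bg[iy, jx] <- FALSE
    core[iy, jx] <- FALSE
  }
  measured <- mean(quiet$octa[core]) - mean(quiet$octa[bg])
  expect_equal(measured, sc$params$contrast,
               tolerance = 0.01 * sc$params$contrast +
                 0.01 * sc$params$contrast)
  # same geometry, different speckle under different noise seeds
  n1 <- render_images(sc, noise_seed = 1)
  n2 <- render_images(sc, noise_seed = 2)
  expect_false(identical(n1$octa, n2$octa))
  expect_identical(render_images(sc, noise_seed = 1)$octa, n1$octa)
})

test_that("rendered landmark crosses are recovered to sub-pixel accuracy", {
  sc <- generate_scene(small_params(8))
  imgs <- render_images(sc)
  set.seed(1)
  approx <- data.frame(x = sc$landmarks$fixed_x + runif(3, -3, 3),
                       y = sc$landmarks$fixed_y + runif(3, -3, 3))
  det <- detect_landmarks(imgs$octa, approx)
  err <- sqrt((det$x - sc$landmarks$fixed_x)^2 +
                (det$y - sc$landmarks$fixed_y)^2)
  expect_lt(max(err), 0.5)
})

test_that("cohort follow-up scenes rescale areas by the squared radius
           factor", {
  co <- generate_cohort(n_eyes = 4, seed = 55,
                        base_params = small_params(55),
                        shrink_laser = 0.6, shrink_observation = 0.9)
  expect_setequal(unique(co$manifest$group), c("LASER", "OBSERVATION"))
  for (eye in co$eyes) {
    f <- if (eye$group == "LASER") 0.6 else 0.9
    for (lab in c("TYPE_A", "TYPE_C")) {
      a0 <- polygon_area_px(get_roi(eye$baseline$octa_truth, lab))
      a1 <- polygon_area_px(get_roi(eye$followup$octa_truth, lab))
      expect_equal(a1, f^2 * a0, tolerance = 1e-9 * a0)
    }
    # ICGA rescaling preserves the cross-modality correspondence
    h1 <- get_roi(eye$followup$icga_truth, "HYPERFLUORESCENCE")
    h0 <- get_roi(eye$baseline$icga_truth, "HYPERFLUORESCENCE")
    expect_equal(polygon_area_px(h1), f^2 * polygon_area_px(h0),
                 tolerance = 1e-6 * polygon_area_px(h0))
  }
  # identical shrinkage of 1 keeps all areas fixed
  co1 <- generate_cohort(n_eyes = 2, seed = 56, base_params = small_params(56),
                         shrink_laser = 1, shrink_observation = 1)
  for (eye in co1$eyes) {
    expect_equal(polygon_area_px(get_roi(eye$followup$octa_truth, "TYPE_A")),
                 polygon_area_px(get_roi(eye$baseline$octa_truth, "TYPE_A")),
                 tolerance = 1e-9)
  }
})
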