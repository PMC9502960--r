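fr_small <- image_frame(128, 128, 12, 12)

test_that("Jaccard identities: self, disjoint, half overlap", {
  a <- sq_roi(20, 20, 30)
  for (m in c("RASTER", "POLYGON")) {
    self <- jaccard_index(a, a, fr_small, m)
    expect_equal(self$jaccard, 1)
    far <- jaccard_index(a, sq_roi(80, 80, 30), fr_small, m)
    expect_equal(far$jaccard, 0)
    expect_equal(far$union_px, far$area_a_px + far$area_b_px,
                 tolerance = 1e-9)
  }
  half <- jaccard_index(sq_roi(0, 0, 20), sq_roi(10, 0, 20), fr_small,
                        "POLYGON")
  expect_equal(half$jaccard, 1 / 3, tolerance = 1e-12)
  expect_equal(half$intersection_px, 200, tolerance = 1e-9)
  expect_equal(half$union_px, 600, tolerance = 1e-9)
})

test_that("overlap results are symmetric and unit-consistent", {
  set.seed(13)
  for (m in c("RASTER", "POLYGON")) {
    a <- random_star_poly(50, 50); b <- random_star_poly(60, 55)
    r1 <- jaccard_index(a, b, fr_small, m)
    r2 <- jaccard_index(b, a, fr_small, m)
    expect_identical(r1$jaccard, r2$jaccard)
    expect_equal(r1$union_px, r1$area_a_px + r1$area_b_px -
                   r1$intersection_px, tolerance = 1e-9)
    expect_lte(r1$intersection_px,
               min(r1$area_a_px, r1$area_b_px) + 1e-9)
    expect_gte(r1$jaccard, 0); expect_lte(r1$jaccard, 1)
    expect_equal(r1$area_a_mm2, r1$area_a_px * px_area_mm2(fr_small))
  }
})

test_that("empty union raises rather than returning 0 or NaN", {
  deg <- roi(list(x = c(1, 2, 3), y = c(1, 2, 3)))   # zero-area
  expect_error(jaccard_index(deg, deg, fr_small, "POLYGON"),
               class = "undefined_overlap_error")
  expect_error(jaccard_index(deg, deg, fr_small, "RASTER"),
               class = "undefined_overlap_error")
})

test_that("POLYGON Jaccard is invariant under a common similarity", {
  set.seed(17)
  ang <- 0.4
  t <- affine_transform(1.6 * cos(ang), -1.6 * sin(ang), 25,
                        1.6 * sin(ang), 1.6 * cos(ang), -10)
  for (i in 1:10) {
    a <- random_star_poly(50, 50); b <- random_star_poly(58, 48)
    j0 <- jaccard_index(a, b, fr_small, "POLYGON")$jaccard
    j1 <- jaccard_index(apply_to_roi(t, a), apply_to_roi(t, b),
                        fr_small, "POLYGON")$jaccard
    expect_equal(j1, j0, tolerance = 1e-9)
  }
})

test_that("POLYGON and RASTER engines agree within the pixel-boundary
           bound on random pairs", {
  set.seed(29)
  for (i in 1:15) {
    a <- random_star_poly(55, 55, rmin = 15, rmax = 35)
    b <- random_star_poly(62, 58, rmin = 15, rmax = 35)
    jp <- jaccard_index(a, b, fr_small, "POLYGON")
    jr <- jaccard_index(a, b, fr_small, "RASTER", supersample = 4L)
    h <- 1 / 4                                   # supersampled cell size
    bound <- 2 * (roi_perimeter(a) + roi_perimeter(b)) * h / jp$union_px
    expect_lt(abs(jp$jaccard - jr$jaccard), bound)
  }
})

test_that("disc pairs reproduce the closed-form lens overlap", {
  fr <- image_frame(512, 512, 12, 12)
  set.seed(31)
  for (i in 1:5) {
    r1 <- runif(1, 40, 90); r2 <- runif(1, 40, 90)
    d <- runif(1, 10, r1 + r2 - 5)
    a <- disc_roi(200, 250, r1)
    b <- disc_roi(200 + d, 250, r2)
    truth_ji <- circle_overlap_area(r1, r2, d) /
      (pi * r1^2 + pi * r2^2 - circle_overlap_area(r1, r2, d))
    expect_equal(jaccard_index(a, b, fr, "POLYGON")$jaccard, truth_ji,
                 tolerance = 0.02)
    expect_equal(jaccard_index(a, b, fr, "RASTER")$jaccard, truth_ji,
                 tolerance = 0.02)
  }
})

test_that("crossmodal concordance maps the ICGA annotation before overlap", {
  fr <- image_frame(256, 256, 12, 12)
  t <- affine_transform(1.05, 0.03, 11, -0.02, 0.96, -7)
  a <- disc_roi(120, 130, 50, label = "TYPE_A")
  # ICGA region = exact affine preimage of the OCTA region
  h <- apply_to_roi(invert_affine(t), a)
  h$label <- "HYPERFLUORESCENCE"
  so <- annotation_set("e1", 0, grader = "g1", rois = list(a))
  si <- annotation_set("e1", 0, grader = "g1", rois = list(h))
  res <- jaccard_index(a, apply_to_roi(t, h, fr), fr, "POLYGON")
  expect_gt(res$jaccard, 1 - 1e-9)
  cc <- crossmodal_concordance(so, si, t, fr, method = "POLYGON")
  expect_equal(cc$jaccard, res$jaccard)
  expect_identical(cc$meta$eye_id, "e1")
  # missing label errors loudly
  so2 <- annotation_set("e1", 0, grader = "g1",
                        rois = list(disc_roi(10, 10, 5, label = "TYPE_B")))
  expect_error(crossmodal_concordance(so2, si, t, fr),
               class = "missing_annotation_error")
  expect_error(crossmodal_concordance(so2, si, t, fr), "TYPE_A")
})

test_that("interobserver agreement validates graders and degrades with
           boundary noise", {
  fr <- image_frame(512, 512, 12, 12)
  truth <- disc_roi(250, 250, 100, label = "TYPE_A")
  mk <- function(g, sigma, seed)
    annotation_set("e1", 0, grader = g,
                   rois = list(simulate_grader(truth, sigma, seed, g)))
  expect_error(interobserver_agreement(mk("g1", 0, 1), mk("g1", 0, 2),
                                       fr, "TYPE_A"),
               class = "usage_error")
  noiseless <- interobserver_agreement(mk("g1", 0, 1), mk("g2", 0, 2),
                                       fr, "TYPE_A", method = "POLYGON")
  expect_equal(noiseless$jaccard, 1)
  ji_at <- function(sigma) {
    median(vapply(1:25, function(s)
      interobserver_agreement(mk("g1", 0, 1), mk("g2", sigma, 1000 + s),
                              fr, "TYPE_A", method = "POLYGON")$jaccard, 0))
  }
  expect_gt(ji_at(2), ji_at(6))
  miss <- annotation_set("e1", 0, grader = "g3", rois = list())
  expect_error(interobserver_agreement(mk("g1", 0, 1), miss, fr, "TYPE_B"),
               class = "missing_annotation_error")
})

test_that("cohort JI summaries use the sample SD and flag n = 1", {
  s1 <- cohort_ji_summary(c(1.0))
  expect_equal(s1$mean, 1); expect_equal(s1$sd, 0); expect_true(s1$n1_flag)
  s2 <- cohort_ji_summary(c(0.4, 0.6))
  expect_equal(s2$mean, 0.5)
  expect_equal(s2$sd, sqrt(0.02), tolerance = 1e-12)
  expect_error(cohort_ji_summary(numeric(0)), class = "empty_input_error")
})
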