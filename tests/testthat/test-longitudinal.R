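mk_meas <- function(eye, tp, group, label, mm2, months = tp) {
  data.frame(eye_id = eye, timepoint = tp, group = group, grader = "g1",
             label = label, area_px = NA_real_, area_mm2 = mm2,
             months = months, stringsAsFactors = FALSE)
}

test_that("change records difference follow-up minus baseline", {
  m <- rbind(mk_meas("e1", 0, "LASER", "TYPE_A", 7.3),
             mk_meas("e1", 2, "LASER", "TYPE_A", 3.4, months = 2))
  bc <- build_changes(m)
  expect_equal(bc$changes$delta_mm2, -3.9)
  expect_equal(bc$changes$relative_change, -3.9 / 7.3)
  expect_equal(bc$changes$followup_timepoint, 2)
  expect_equal(bc$changes$followup_months, 2)
  expect_equal(nrow(bc$exclusions), 0)
})

test_that("labels absent at one visit are excluded with a report", {
  m <- rbind(mk_meas("e1", 0, "LASER", "TYPE_A", 7.3),
             mk_meas("e1", 0, "LASER", "TYPE_B", 4.0),
             mk_meas("e1", 1, "LASER", "TYPE_A", 3.4))
  bc <- build_changes(m)
  expect_equal(nrow(bc$changes), 1)
  expect_equal(bc$exclusions$eye_id, "e1")
  expect_equal(bc$exclusions$label, "TYPE_B")
  expect_equal(bc$exclusions$missing_at, "followup")
  # zero baseline flags the relative change undefined
  m2 <- rbind(mk_meas("e2", 0, "LASER", "TYPE_C", 0),
              mk_meas("e2", 1, "LASER", "TYPE_C", 0.5))
  bc2 <- build_changes(m2)
  expect_false(bc2$changes$relative_defined)
  expect_true(is.na(bc2$changes$relative_change))
  expect_error(build_changes(mk_meas("e3", 1, "LASER", "TYPE_A", 1)),
               class = "missing_baseline_error")
})

test_that("build_changes is order-invariant and additive over eyes", {
  set.seed(23)
  rows <- list()
  for (e in 1:6) for (lab in c("TYPE_A", "TYPE_C")) {
    rows[[length(rows) + 1]] <- mk_meas(sprintf("e%d", e), 0, "LASER",
                                        lab, runif(1, 2, 9))
    rows[[length(rows) + 1]] <- mk_meas(sprintf("e%d", e), 1, "LASER",
                                        lab, runif(1, 1, 5))
  }
  m <- do.call(rbind, rows)
  bc1 <- build_changes(m)
  bc2 <- build_changes(m[sample(nrow(m)), ])
  ord <- function(d) d[order(d$eye_id, d$label), ]
  expect_equal(ord(bc1$changes), ord(bc2$changes), ignore_attr = TRUE)
  expect_equal(sum(bc1$changes$delta_mm2),
               sum(bc1$changes$followup_mm2) -
                 sum(bc1$changes$baseline_mm2), tolerance = 1e-12)
})

test_that("paired follow-up test reports pooled and per-group results", {
  set.seed(27)
  rows <- list()
  for (e in 1:12) {
    g <- if (e %% 2) "LASER" else "OBSERVATION"
    b <- runif(1, 4, 10)
    rows[[length(rows) + 1]] <- mk_meas(sprintf("e%d", e), 0, g, "TYPE_A", b)
    rows[[length(rows) + 1]] <- mk_meas(sprintf("e%d", e), 1, g, "TYPE_A",
                                        b * 0.4 + rnorm(1, 0, 0.1))
  }
  bc <- build_changes(do.call(rbind, rows))
  res <- paired_followup_test(bc$changes, "TYPE_A")
  expect_equal(res$n, 12)
  expect_lt(res$pooled$p_value, 0.01)
  expect_setequal(names(res$by_group), c("LASER", "OBSERVATION"))
  # all-zero deltas propagate the degenerate-input error
  same <- rbind(mk_meas("e1", 0, "LASER", "TYPE_A", 5),
                mk_meas("e1", 1, "LASER", "TYPE_A", 5),
                mk_meas("e2", 0, "LASER", "TYPE_A", 3),
                mk_meas("e2", 1, "LASER", "TYPE_A", 3))
  bs <- build_changes(same)
  expect_error(paired_followup_test(bs$changes, "TYPE_A"),
               class = "degenerate_input_error")
  expect_error(paired_followup_test(bc$changes, "TYPE_B"),
               class = "missing_annotation_error")
})

test_that("balanced two-way ANOVA reproduces the closed-form decomposition", {
  # 2 groups x 3 labels x n=4, additive truth; type II == classical sums of
  # squares in the balanced case, computed here directly from cell means
  set.seed(31)
  grid <- expand.grid(rep = 1:4, group = c("LASER", "OBSERVATION"),
                      label = c("TYPE_A", "TYPE_B", "TYPE_C"))
  grid$delta_mm2 <- round(rnorm(nrow(grid), -2, 1), 2) +
    ifelse(grid$group == "LASER", -0.8, 0)
  grid$eye_id <- sprintf("e%02d", seq_len(nrow(grid)))
  cmp <- group_change_comparison(grid)
  y <- grid$delta_mm2
  gm <- mean(y)
  a_means <- tapply(y, grid$group, mean)
  b_means <- tapply(y, grid$label, mean)
  cell_means <- tapply(y, interaction(grid$group, grid$label), mean)
  ss_a <- 12 * sum((a_means - gm)^2)          # n * levels(label) per group
  ss_cells <- 4 * sum((cell_means - gm)^2)
  ss_b <- 8 * sum((b_means - gm)^2)
  ss_ab <- ss_cells - ss_a - ss_b
  ss_e <- sum((y - ave(y, interaction(grid$group, grid$label)))^2)
  f_a <- (ss_a / 1) / (ss_e / (24 - 6))
  expect_equal(cmp$group_effect$F, f_a, tolerance = 1e-9)
  expect_equal(cmp$group_effect$df, c(1, 18))
  expect_equal(cmp$group_effect$p, pf(f_a, 1, 18, lower.tail = FALSE),
               tolerance = 1e-9)
  expect_setequal(cmp$per_label$label, c("TYPE_A", "TYPE_B", "TYPE_C"))
  expect_true(all(is.finite(cmp$per_label$p_mw)))
})

test_that("group comparison validates group presence and flags sparse
           labels", {
  base <- data.frame(eye_id = sprintf("e%d", 1:8),
                     group = rep("LASER", 8),
                     label = rep(c("TYPE_A", "TYPE_C"), 4),
                     delta_mm2 = rnorm(8), stringsAsFactors = FALSE)
  expect_error(group_change_comparison(base),
               class = "configuration_error")
  both <- base
  both$group <- rep(c("LASER", "LASER", "OBSERVATION", "OBSERVATION"), 2)
  extra <- data.frame(eye_id = "e9", group = "LASER", label = "TYPE_B",
                      delta_mm2 = 0.5, stringsAsFactors = FALSE)
  cmp <- group_change_comparison(rbind(both, extra))
  expect_identical(cmp$flagged_labels, "TYPE_B")
  expect_false("TYPE_B" %in% cmp$per_label$label)
})

test_that("a uniformly shrunken synthetic cohort recovers the quadratic
           area law", {
  co <- generate_cohort(n_eyes = 6, seed = 41,
                        base_params = scene_params(
                          seed = 41, frame = image_frame(512, 512, 12, 12)),
                        shrink_laser = 0.5, shrink_observation = 0.5)
  rows <- list()
  for (eye in co$eyes) for (tp in 0:1) {
    sc <- if (tp == 0) eye$baseline else eye$followup
    set <- sc$octa_truth
    set$eye_id <- eye$eye_id; set$timepoint <- tp; set$group <- eye$group
    rows[[length(rows) + 1]] <- measure_areas(set, sc$octa_frame)
  }
  bc <- build_changes(do.call(rbind, rows))
  expect_gt(nrow(bc$changes), 0)
  expect_equal(bc$changes$relative_change,
               rep(-0.75, nrow(bc$changes)), tolerance = 1e-9)
})
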