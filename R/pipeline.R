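# Orchestration: simulate a cohort bundle to disk, then run the concordance
# and longitudinal analyses from the files alone. All outputs are pure
# functions of (inputs, config, seed); every report carries a config hash.

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(jsonlite::serializeJSON(config[order(names(config))]), tmp)
  unname(tools::md5sum(tmp))
}

roi_zip_name <- function(grader, modality) {
  sprintf("rois_%s_%s.zip", grader, modality)
}

# write one eye/timepoint directory: ROI zips, landmarks, truth, images
write_visit_dir <- function(dir, scene, annotations, graders, render) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(scene$landmarks, file.path(dir, "landmarks.csv"),
            row.names = FALSE)
  tsets <- list(truth_octa = scene$octa_truth, truth_icga = scene$icga_truth)
  zips <- c(setNames(tsets, c(roi_zip_name("truth", "octa"),
                              roi_zip_name("truth", "icga"))),
            setNames(annotations,
                     vapply(names(annotations), function(nm) {
                       parts <- strsplit(nm, "_")[[1]]
                       roi_zip_name(parts[2], parts[3])
                     }, "")))
  for (nm in names(zips)) {
    set <- zips[[nm]]
    rois <- set$rois
    names(rois) <- vapply(rois, function(r) r$label, "")
    write_roi_zip(rois, file.path(dir, nm))
  }
  write_affine_json(scene$true_affine, file.path(dir, "true_affine.json"))
  jsonlite::write_json(list(analytic_mm2 = scene$analytic_mm2,
                            center = scene$center,
                            seed = scene$params$seed),
                       file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  if (render) {
    imgs <- render_images(scene)
    write_raster_file(imgs$octa, file.path(dir, "octa.png"))
    write_raster_file(imgs$icga, file.path(dir, "icga.png"))
    for (m in c("octa", "icga")) {
      set <- if (m == "octa") scene$octa_truth else scene$icga_truth
      fr <- if (m == "octa") scene$octa_frame else scene$icga_frame
      for (r in set$rois)
        write_mask_image(roi_to_mask(r, fr),
                         file.path(dir, sprintf("mask_%s_%s.png",
                                                m, r$label)))
    }
  }
}

#' Simulate a cohort and write the scene bundle to disk
#'
#' @param config list with `out_dir`, `seed`, and optionally `n_eyes`,
#'   `shrink_laser`, `shrink_observation`, `grader_sigmas`, `render`
#'   (default FALSE: skip rendered images and masks), plus any
#'   [scene_params()] overrides under `scene`.
#' @return the [generate_cohort()] result, invisibly; the bundle (manifest,
#'   frame config, per-visit ROI zips, landmark CSVs, truth JSONs) is
#'   written under `out_dir`.
#' @export
run_simulate <- function(config) {
  if (is.null(config$out_dir) || is.null(config$seed))
    oc_stop("configuration_error", "run_simulate needs out_dir and seed")
  sp <- do.call(scene_params, c(list(seed = as.integer(config$seed)),
                                config$scene %||% list()))
  cohort <- generate_cohort(
    n_eyes = config$n_eyes %||% 39L, seed = as.integer(config$seed),
    base_params = sp,
    shrink_laser = config$shrink_laser %||% 0.7,
    shrink_observation = config$shrink_observation %||% 0.7,
    grader_sigmas = config$grader_sigmas %||% c(g1 = 18, g2 = 18))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  graders <- names(config$grader_sigmas %||% c(g1 = 18, g2 = 18))
  rows <- list()
  for (eye in cohort$eyes) {
    for (tp in c(0L, 1L)) {
      vdir <- file.path(out, eye$eye_id, sprintf("t%d", tp))
      scene <- if (tp == 0L) eye$baseline else eye$followup
      ann <- eye$annotations[grepl(sprintf("^t%d_", tp),
                                   names(eye$annotations))]
      write_visit_dir(vdir, scene, ann, graders,
                      render = isTRUE(config$render))
      rows[[length(rows) + 1]] <- data.frame(
        eye_id = eye$eye_id, timepoint = tp, group = eye$group,
        months = if (tp == 0L) 0 else eye$months,
        visit_dir = file.path(eye$eye_id, sprintf("t%d", tp)),
        stringsAsFactors = FALSE)
    }
  }
  write.csv(do.call(rbind, rows), file.path(out, "manifest.csv"),
            row.names = FALSE)
  fr <- sp$frame
  jsonlite::write_json(list(width = fr$width, height = fr$height,
                            fov_width_mm = fr$fov_width,
                            fov_height_mm = fr$fov_height,
                            modality = fr$modality,
                            config_hash = config_hash(config)),
                       file.path(out, "frame.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(cohort)
}

read_visit_rois <- function(vdir, grader, modality) {
  path <- file.path(vdir, roi_zip_name(grader, modality))
  if (!file.exists(path))
    oc_stop("missing_annotation_error", "ROI bundle missing: %s", path)
  rois <- read_roi_zip(path)
  for (nm in names(rois)) rois[[nm]]$label <- nm
  rois
}

visit_annotation_set <- function(vdir, row, grader, modality) {
  rois <- read_visit_rois(vdir, grader, modality)
  annotation_set(row$eye_id, row$timepoint,
                 if (is.na(row$group)) NA_character_ else row$group,
                 grader, unname(rois))
}

#' Run the cross-modality concordance analysis on a bundle
#'
#' Per eye at baseline: register ICGA to OCTA from the landmark CSV, compute
#' the cross-modality Jaccard index per grader, the interobserver Jaccard
#' index per label, and the type A vs hyperfluorescence areas. Failures are
#' recorded per eye and the run continues.
#'
#' @param config list with `bundle_dir`, optionally `graders`
#'   (default c("g1","g2")), `method` (default "RASTER"), `out_dir`
#'   (default `<bundle_dir>/results`).
#' @return list with `per_eye` (data.frame of overlap rows), `summary`
#'   (per-grader mean +/- SD JI and interobserver summary), `area_tests`,
#'   `failed_eyes`, `status` (0 ok, 1 partial failures). CSV and JSON
#'   reports are written under `out_dir`.
#' @export
run_concordance <- function(config) {
  bdir <- config$bundle_dir
  if (is.null(bdir) || !file.exists(file.path(bdir, "manifest.csv")))
    oc_stop("configuration_error", "bundle_dir with manifest.csv required")
  manifest <- read.csv(file.path(bdir, "manifest.csv"))
  if (!nrow(manifest)) oc_stop("empty_input_error", "manifest is empty")
  frame <- read_frame_config(file.path(bdir, "frame.json"))
  graders <- config$graders %||% c("g1", "g2")
  method <- config$method %||% "RASTER"
  out_dir <- config$out_dir %||% file.path(bdir, "results")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  base <- manifest[manifest$timepoint == 0, ]
  rows <- list(); areas <- list(); failed <- character()
  for (k in seq_len(nrow(base))) {
    row <- base[k, ]
    vdir <- file.path(bdir, row$visit_dir)
    res <- tryCatch({
      lm <- read_landmarks_csv(file.path(vdir, "landmarks.csv"))
      reg <- estimate_affine(lm)
      eye_rows <- list()
      sets <- list()
      for (g in graders) {
        so <- visit_annotation_set(vdir, row, g, "octa")
        si <- visit_annotation_set(vdir, row, g, "icga")
        sets[[g]] <- list(octa = so, icga = si)
        cc <- crossmodal_concordance(so, si, reg$transform, frame, method)
        eye_rows[[length(eye_rows) + 1]] <- data.frame(
          eye_id = row$eye_id, timepoint = row$timepoint,
          graders = g, label = cc$meta$label, comparison = "crossmodal",
          method = method, area_a_mm2 = cc$area_a_mm2,
          area_b_mm2 = cc$area_b_mm2,
          intersection_mm2 = cc$intersection_mm2,
          union_mm2 = cc$union_mm2, jaccard = cc$jaccard,
          rmse_px = reg$rmse, stringsAsFactors = FALSE)
        areas[[length(areas) + 1]] <- data.frame(
          eye_id = row$eye_id, grader = g,
          typeA_mm2 = cc$area_a_mm2, hyper_mm2 = cc$area_b_mm2,
          stringsAsFactors = FALSE)
      }
      if (length(graders) >= 2) {
        for (m in c("octa", "icga")) {
          lab <- if (m == "octa") "TYPE_A" else "HYPERFLUORESCENCE"
          io <- interobserver_agreement(sets[[graders[1]]][[m]],
                                        sets[[graders[2]]][[m]],
                                        frame, lab, method)
          eye_rows[[length(eye_rows) + 1]] <- data.frame(
            eye_id = row$eye_id, timepoint = row$timepoint,
            graders = paste(graders[1:2], collapse = "+"), label = lab,
            comparison = "interobserver", method = method,
            area_a_mm2 = io$area_a_mm2, area_b_mm2 = io$area_b_mm2,
            intersection_mm2 = io$intersection_mm2,
            union_mm2 = io$union_mm2, jaccard = io$jaccard,
            rmse_px = NA_real_, stringsAsFactors = FALSE)
        }
      }
      do.call(rbind, eye_rows)
    }, octaconcord_error = function(e) e)
    if (inherits(res, "error")) {
      failed <- c(failed, row$eye_id)
      warning(sprintf("eye %s failed: %s", row$eye_id,
                      conditionMessage(res)), call. = FALSE)
    } else rows[[length(rows) + 1]] <- res
  }
  if (!length(rows))
    oc_stop("empty_input_error", "no eye could be processed")
  per_eye <- do.call(rbind, rows)
  area_df <- do.call(rbind, areas)

  summary <- list()
  for (g in graders) {
    sel <- per_eye$comparison == "crossmodal" & per_eye$graders == g
    summary[[paste0("crossmodal_", g)]] <- cohort_ji_summary(
      per_eye$jaccard[sel])
  }
  for (lab in unique(per_eye$label[per_eye$comparison == "interobserver"]))
    summary[[paste0("interobserver_", lab)]] <- cohort_ji_summary(
      per_eye$jaccard[per_eye$comparison == "interobserver" &
                        per_eye$label == lab])
  area_tests <- lapply(setNames(graders, graders), function(g) {
    sub <- area_df[area_df$grader == g, ]
    compare_paired_areas(sub$typeA_mm2, sub$hyper_mm2, "WILCOXON")
  })

  hash <- config_hash(config)
  write.csv(per_eye, file.path(out_dir, "concordance.csv"),
            row.names = FALSE)
  jsonlite::write_json(
    list(config_hash = hash, method = method, summary = summary,
         area_tests = area_tests, failed_eyes = failed),
    file.path(out_dir, "concordance.json"), auto_unbox = TRUE, digits = NA,
    force = TRUE)
  list(per_eye = per_eye, summary = summary, area_tests = area_tests,
       failed_eyes = failed, status = if (length(failed)) 1L else 0L,
       config_hash = hash)
}

#' Run the longitudinal change analysis on a bundle
#'
#' Measures per-label areas of one grader's annotations at baseline and the
#' latest visit of every eye, builds change records, tests the baseline-vs-
#' follow-up difference per label (Wilcoxon signed rank), and compares the
#' changes between the laser and observation groups (type-II two-way ANOVA
#' with a rank-based companion).
#'
#' @param config list with `bundle_dir`, optionally `grader` (default
#'   `"g1"`; `"truth"` uses the ground-truth polygons), `out_dir`.
#' @return list with `changes`, `exclusions`, `per_label_tests`,
#'   `group_comparison`, `config_hash`.
#' @export
run_longitudinal <- function(config) {
  bdir <- config$bundle_dir
  if (is.null(bdir) || !file.exists(file.path(bdir, "manifest.csv")))
    oc_stop("configuration_error", "bundle_dir with manifest.csv required")
  manifest <- read.csv(file.path(bdir, "manifest.csv"))
  if (!nrow(manifest)) oc_stop("empty_input_error", "manifest is empty")
  frame <- read_frame_config(file.path(bdir, "frame.json"))
  grader <- config$grader %||% "g1"
  out_dir <- config$out_dir %||% file.path(bdir, "results")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  meas <- list()
  for (k in seq_len(nrow(manifest))) {
    row <- manifest[k, ]
    vdir <- file.path(bdir, row$visit_dir)
    set <- visit_annotation_set(vdir, row, grader, "octa")
    m <- measure_areas(set, frame)
    m <- m[m$label %in% c("TYPE_A", "TYPE_B", "TYPE_C"), ]
    if (nrow(m)) m$months <- row$months
    meas[[k]] <- m
  }
  bc <- build_changes(do.call(rbind, meas))
  labs <- unique(bc$changes$label)
  per_label <- lapply(setNames(labs, labs), function(lab)
    paired_followup_test(bc$changes, lab))
  group_cmp <- tryCatch(group_change_comparison(bc$changes),
                        octaconcord_error = function(e)
                          list(error = conditionMessage(e)))
  hash <- config_hash(config)
  write.csv(bc$changes, file.path(out_dir, "changes.csv"),
            row.names = FALSE)
  jsonlite::write_json(
    list(config_hash = hash, grader = grader,
         per_label_tests = per_label,
         group_effect = group_cmp$group_effect %||% NULL,
         per_label_group = group_cmp$per_label %||% NULL,
         exclusions = bc$exclusions),
    file.path(out_dir, "longitudinal.json"), auto_unbox = TRUE,
    digits = NA, force = TRUE)
  list(changes = bc$changes, exclusions = bc$exclusions,
       per_label_tests = per_label, group_comparison = group_cmp,
       config_hash = hash)
}
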