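# Baseline-vs-follow-up change in per-type lesion areas and the laser-vs-
# observation comparison of those changes.

#' Build per-eye, per-label change records
#'
#' Baseline is the timepoint-0 measurement; follow-up is the latest
#' timepoint per eye (follow-up horizons vary between eyes and are recorded
#' per eye). Eyes missing a label at either timepoint are listed in an
#' exclusion report, never silently dropped.
#'
#' @param measurements data.frame as returned by [measure_areas()]
#'   (columns eye_id, timepoint, group, label, area_mm2; optionally
#'   `months`). Rows from several visits may be stacked; if several graders
#'   are present, filter to one (or a consensus) first.
#' @return list with `changes` (eye_id, group, label, baseline_mm2,
#'   followup_mm2, delta_mm2, relative_change, relative_defined,
#'   followup_timepoint, followup_months) and `exclusions` (eye_id, label,
#'   missing_at).
#' @export
build_changes <- function(measurements) {
  m <- as.data.frame(measurements)
  if (!nrow(m)) oc_stop("empty_input_error", "no measurements given")
  eyes <- unique(m$eye_id)
  changes <- list(); excl <- list()
  for (eye in eyes) {
    me <- m[m$eye_id == eye, ]
    if (!any(me$timepoint == 0))
      oc_stop("missing_baseline_error",
              "eye %s has no baseline (timepoint 0) measurement", eye)
    tf <- max(me$timepoint)
    if (tf == 0) next                      # no follow-up visit for this eye
    base <- me[me$timepoint == 0, ]
    foll <- me[me$timepoint == tf, ]
    for (lab in union(base$label, foll$label)) {
      b <- base[base$label == lab, ]
      f <- foll[foll$label == lab, ]
      if (!nrow(b) || !nrow(f)) {
        excl[[length(excl) + 1]] <- data.frame(
          eye_id = eye, label = lab,
          missing_at = if (nrow(b)) "followup" else "baseline",
          stringsAsFactors = FALSE)
        next
      }
      delta <- f$area_mm2[1] - b$area_mm2[1]
      changes[[length(changes) + 1]] <- data.frame(
        eye_id = eye, group = b$group[1], label = lab,
        baseline_mm2 = b$area_mm2[1], followup_mm2 = f$area_mm2[1],
        delta_mm2 = delta,
        relative_change = if (b$area_mm2[1] > 0) delta / b$area_mm2[1]
        else NA_real_,
        relative_defined = b$area_mm2[1] > 0,
        followup_timepoint = tf,
        followup_months = if ("months" %in% names(f)) f$months[1]
        else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  list(changes = if (length(changes)) do.call(rbind, changes)
       else data.frame(),
       exclusions = if (length(excl)) do.call(rbind, excl)
       else data.frame(eye_id = character(), label = character(),
                       missing_at = character()))
}

#' Paired baseline-vs-follow-up test for one lesion label
#'
#' Wilcoxon signed-rank on the (baseline, follow-up) area pairs via
#' [compare_paired_areas()]; reported pooled over treatment groups and,
#' when both groups are present, per group.
#'
#' @param changes the `changes` data.frame from [build_changes()].
#' @param label lesion label to test.
#' @param test passed to [compare_paired_areas()].
#' @return list with `pooled` and (possibly empty) `by_group` test results,
#'   plus `label` and `n`.
#' @export
paired_followup_test <- function(changes, label, test = "WILCOXON") {
  ch <- changes[changes$label == label, ]
  if (!nrow(ch))
    oc_stop("missing_annotation_error", "no change records for label %s",
            label)
  pooled <- compare_paired_areas(ch$baseline_mm2, ch$followup_mm2, test)
  by_group <- list()
  for (g in unique(ch$group[!is.na(ch$group)])) {
    sub <- ch[ch$group == g, ]
    if (nrow(sub) >= 2 && any(sub$baseline_mm2 != sub$followup_mm2))
      by_group[[g]] <- compare_paired_areas(sub$baseline_mm2,
                                            sub$followup_mm2, test)
  }
  list(label = label, n = nrow(ch), pooled = pooled, by_group = by_group)
}

#' Compare area changes between treatment groups
#'
#' Two-way ANOVA of the area change on group (laser vs observation) and
#' lesion label with type-II sums of squares for the unbalanced factorial,
#' reporting the group main effect; per label, the one-way group F test and
#' a rank-based Mann-Whitney comparison as a robustness companion. Labels
#' with a group absent are flagged and omitted from the factorial model.
#'
#' @param changes the `changes` data.frame from [build_changes()].
#' @return list with `group_effect` (F, df, p), `anova_table`, `per_label`
#'   data.frame (label, n per group, F/p, Mann-Whitney W/p), and
#'   `flagged_labels`.
#' @export
group_change_comparison <- function(changes) {
  ch <- changes[!is.na(changes$group), ]
  groups <- unique(ch$group)
  if (length(groups) < 2)
    oc_stop("configuration_error",
            "both treatment groups required; only %s present",
            paste(groups, collapse = ", "))
  tab <- table(ch$label, ch$group)
  ok_labels <- rownames(tab)[apply(tab > 0, 1, all)]
  flagged <- setdiff(rownames(tab), ok_labels)
  if (length(ok_labels) < 2)
    oc_stop("configuration_error",
            "two-way ANOVA needs >= 2 labels with both groups present")
  sub <- ch[ch$label %in% ok_labels, ]
  sub$group <- factor(sub$group)
  sub$label <- factor(sub$label)
  has_int <- all(tab[ok_labels, ] > 1)
  fit <- if (has_int) lm(delta_mm2 ~ group * label, data = sub)
  else lm(delta_mm2 ~ group + label, data = sub)
  an <- car::Anova(fit, type = "II")
  gi <- match("group", rownames(an))
  ri <- match("Residuals", rownames(an))
  group_effect <- list(F = an$`F value`[gi], df = c(an$Df[gi], an$Df[ri]),
                       p = an$`Pr(>F)`[gi])
  per_label <- do.call(rbind, lapply(ok_labels, function(lab) {
    s <- ch[ch$label == lab, ]
    g1 <- s$delta_mm2[s$group == groups[1]]
    g2 <- s$delta_mm2[s$group == groups[2]]
    fv <- pv <- NA_real_
    if (length(g1) > 1 && length(g2) > 1) {
      a1 <- anova(lm(delta_mm2 ~ group, data = s))
      fv <- a1$`F value`[1]; pv <- a1$`Pr(>F)`[1]
    }
    mw <- suppressWarnings(stats::wilcox.test(g1, g2))
    data.frame(label = lab, n_g1 = length(g1), n_g2 = length(g2),
               F = fv, p_anova = pv,
               W = unname(mw$statistic), p_mw = mw$p.value,
               stringsAsFactors = FALSE)
  }))
  list(groups = groups, group_effect = group_effect, anova_table = an,
       per_label = per_label, flagged_labels = flagged)
}
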