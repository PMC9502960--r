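#!/usr/bin/env Rscript
# Longitudinal change in lesion areas: baseline vs latest follow-up per eye
# for the grader-1 annotations, Wilcoxon signed-rank per lesion type, and
# the laser-vs-observation comparison of the changes (type-II two-way ANOVA
# with a rank-based companion). Reads results/bundle/; writes
# results/longitudinal/.

suppressPackageStartupMessages(library(octaconcord))

res <- run_longitudinal(list(bundle_dir = file.path("results", "bundle"),
                             grader = "g1",
                             out_dir = file.path("results", "longitudinal")))

for (lab in names(res$per_label_tests)) {
  ch <- res$changes[res$changes$label == lab, ]
  t <- res$per_label_tests[[lab]]
  b <- summarize_areas(ch$baseline_mm2, "MEDIAN_IQR")
  f <- summarize_areas(ch$followup_mm2, "MEDIAN_IQR")
  cat(sprintf(
    "%s: baseline %.2f (IQR %.2f-%.2f) -> follow-up %.2f (IQR %.2f-%.2f) mm^2, Wilcoxon p = %.2g (n = %d)\n",
    lab, b$center, b$spread_low, b$spread_high,
    f$center, f$spread_low, f$spread_high, t$pooled$p_value, t$n))
}
g <- res$group_comparison
cat(sprintf(
  "Group effect on area change (laser vs observation): F(%d, %d) = %.2f, p = %.3f\n",
  g$group_effect$df[1], g$group_effect$df[2], g$group_effect$F,
  g$group_effect$p))
print(g$per_label, row.names = FALSE, digits = 3)
if (nrow(res$exclusions))
  cat(sprintf("%d (eye, label) pairs excluded (missing at one visit).\n",
              nrow(res$exclusions)))
cat("Change table: results/longitudinal/changes.csv\n")
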