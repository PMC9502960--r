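#!/usr/bin/env Rscript
# Sensitivity of the measured cross-modality Jaccard index to the true
# boundary discrepancy between modalities: sweep the generator's
# icga_boundary_sigma_px over a grid, run the registration + overlap
# pipeline on truth annotations (50 seeds per level), and tabulate the
# median JI. Writes results/ji_vs_sigma.csv.

suppressPackageStartupMessages(library(octaconcord))

sigmas <- c(0, 2, 4, 8, 16, 32, 45, 64)
rows <- lapply(sigmas, function(sig) {
  ji <- vapply(1:50, function(s) {
    sc <- generate_scene(scene_params(seed = s,
                                      icga_boundary_sigma_px = sig))
    reg <- estimate_affine(sc$landmarks)
    crossmodal_concordance(sc$octa_truth, sc$icga_truth, reg$transform,
                           sc$octa_frame, method = "POLYGON")$jaccard
  }, 0)
  data.frame(icga_boundary_sigma_px = sig, median_ji = median(ji),
             q25 = unname(quantile(ji, 0.25)),
             q75 = unname(quantile(ji, 0.75)), n = length(ji))
})
tab <- do.call(rbind, rows)
dir.create("results", showWarnings = FALSE)
write.csv(tab, file.path("results", "ji_vs_sigma.csv"), row.names = FALSE)
cat("Median cross-modality JI by true boundary discrepancy (px):\n")
print(tab, row.names = FALSE, digits = 3)
cat(sprintf("JI decreases monotonically: %s\n",
            all(diff(tab$median_ji) < 0)))
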