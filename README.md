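# octaconcord

Cross-modality lesion concordance for choriocapillaris OCTA and ICGA in
central serous chorioretinopathy (CSC).

In CSC, choroidal hyperpermeability is demonstrated with indocyanine green
angiography (ICGA); swept-source OCT angiography (SS-OCTA) shows
corresponding dye-free abnormalities on the en-face choriocapillaris slab
(type A coarse granulated hyper-reflective areas, type B dark halos, type C
hypo-reflective spots). This package is for image-analysis and reading-center
work that asks how well the two modalities agree: it registers the frames
from user-marked landmarks, measures the spatial overlap of graders'
annotations, converts areas to mm², and compares lesion-area change over
follow-up between treatment arms.

The core quantities:

* a six-coefficient planar affine `(u, v) = (a00·x + a01·y + a02,
  a10·x + a11·y + a12)`, estimated from ≥ 3 landmark pairs (exact
  interpolation at 3, least squares above), mapping the moving ICGA frame
  onto the fixed OCTA grid;
* the Jaccard index `JI = |A ∩ B| / |A ∪ B|` between the registered
  annotations, computed by a raster engine on the fixed pixel grid with an
  exact polygon-clipping oracle beside it;
* per-type lesion areas in mm², Wilcoxon signed-rank tests of
  baseline-vs-follow-up change, and a type-II two-way ANOVA (plus rank-based
  companion) for the laser-vs-observation comparison.

Annotations are exchanged as ImageJ ROI files: the package reads and writes
the `.roi` binary format (polygon/freehand/traced/rect/oval, composite
multi-ring selections, sub-pixel coordinates) and `.zip` bundles. Because
the underlying clinical images are not distributable, a fully deterministic
synthetic scene generator provides ground-truthed paired-modality cohorts
(known inter-modality affine, lesion taxonomy with exact containment,
simulated graders with controllable boundary noise) on which every stage of
the pipeline is validated.

## Worked example

Simulate a 39-eye, two-grader, two-visit cohort to disk and run both
analyses (this is exactly what the numbered scripts under `analysis/` do):

```r
library(octaconcord)

run_simulate(list(out_dir = "results/bundle", seed = 1, n_eyes = 39))
conc <- run_concordance(list(bundle_dir = "results/bundle"))
long <- run_longitudinal(list(bundle_dir = "results/bundle", grader = "g1"))
```

Output of `analysis/01_simulate_cohort.R`, `02_concordance.R`,
`03_longitudinal.R` at seed 1:

```
Simulated 39 eyes (seed 1): 20 observation, 19 laser.
Type B halo present in 27/39 eyes (69.2%).

Cross-modality Jaccard index, type A vs hyperfluorescence:
  grader 1: 0.53 +/- 0.13 (n = 39)
  grader 2: 0.53 +/- 0.13 (n = 39)
Interobserver agreement:
  type A on OCTA:         0.72 +/- 0.10 (n = 39)
  hyperfluorescence ICGA: 0.72 +/- 0.09 (n = 39)

TYPE_A: baseline 6.78 (IQR 4.86-8.05) -> follow-up 3.50 (IQR 2.26-4.26) mm^2, Wilcoxon p = 5.5e-08 (n = 39)
TYPE_B: baseline 4.69 (IQR 3.00-5.91) -> follow-up 2.40 (IQR 1.60-3.39) mm^2, Wilcoxon p = 0.0008 (n = 27)
TYPE_C: baseline 0.31 (IQR 0.26-0.36) -> follow-up 0.15 (IQR 0.14-0.19) mm^2, Wilcoxon p = 7.5e-08 (n = 39)
Group effect on area change (laser vs observation): F(1, 99) = 0.44, p = 0.511
```

Reading: the two modalities show moderate spatial concordance (mean JI
about 0.5) while the two graders agree well with each other (about 0.7);
every lesion type shrinks significantly over follow-up, with no detectable
difference between the laser and observation arms — the structure the
pipeline is designed to measure. `analysis/04_noise_sensitivity.R` sweeps
the true inter-modality boundary discrepancy and tabulates how the median
JI decays with it.

Lower-level functions (`read_imagej_roi()`, `estimate_affine()`,
`jaccard_index()`, `measure_areas()`, `compare_paired_areas()`,
`generate_scene()`, ...) expose each stage individually; see the package
help and the vignette in `vignettes/lesion-concordance.Rmd` for the model,
conventions, and generator details.

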