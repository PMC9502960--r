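---
title: "Quantifying cross-modality lesion concordance between choriocapillaris OCTA and ICGA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cross-modality lesion concordance between choriocapillaris OCTA and ICGA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement problem

In central serous chorioretinopathy (CSC), choroidal vascular
hyperpermeability is classically demonstrated with indocyanine green
angiography (ICGA), an invasive dye-based exam. Swept-source OCT angiography
(SS-OCTA) images the choriocapillaris without dye and shows a taxonomy of
flow abnormalities on the en-face choriocapillaris slab:

* **type A** — a coarse granulated hyper-reflective area;
* **type B** — a roundish dark halo around type A, associated with
  subretinal fluid shadowing;
* **type C** — coarse granulated hypo-reflective spots inside type A.

The clinically interesting question is how well the dye-free OCTA lesions
stand in for the ICGA findings: does the type A area coincide spatially with
the mid-phase ICGA hyperfluorescence, and do the OCTA lesion areas shrink
after treatment or observation? `octaconcord` implements that measurement
pipeline end to end:

1. **Registration.** The two devices produce frames in different coordinate
   systems. Three (or more) user-specified landmark pairs, marked on both
   modalities, determine a planar affine transform
   $(u, v) = (a_{00}x + a_{01}y + a_{02},\; a_{10}x + a_{11}y + a_{12})$.
   With exactly three non-collinear pairs the transform interpolates them
   exactly; with more it is the least-squares fit. ICGA is treated as the
   moving image and the OCTA choriocapillaris slab as the fixed frame, so
   every overlap is measured on one device's pixel grid and mm scale
   (a convention the output metadata records).
2. **Annotation.** Lesions are delineated by human graders with the ImageJ
   ROI tool; the package reads and writes the ImageJ `.roi` binary format
   (and `.zip` bundles) directly, including composite multi-ring selections
   and sub-pixel coordinates. Regions follow the even-odd fill rule, so one
   ROI can hold disjoint components (multifocal type C) and holes.
3. **Overlap.** Concordance between an OCTA annotation $A$ and a
   registered ICGA annotation $B$ is the Jaccard index
   $JI = |A \cap B| / |A \cup B|$. Interobserver agreement between two
   graders' annotations of the same frame is measured the same way, without
   registration.
4. **Areas and change.** Polygon areas convert to mm² through each frame's
   field of view. Baseline-to-follow-up changes are tested per lesion type
   with the Wilcoxon signed-rank test, and the change is compared between
   treatment arms (laser vs observation) with a type-II two-way ANOVA plus
   a rank-based Mann–Whitney companion.

Because no clinical images are distributed with the study this package
emulates, every stage is validated on synthetic paired-modality scenes with
exact ground truth.

## Overlap engines and their roles

Two independent engines compute every overlap:

* **RASTER** (the primary method): both regions are rasterized on the fixed
  frame by the pixel-center rule — cell $(i, j)$ is inside iff the point
  $(x{=}j, y{=}i)$ lies in the even-odd fill — and intersection/union are
  pixel counts. This matches the resolution at which graders actually
  annotate.
* **POLYGON** (the oracle): exact even-odd polygon clipping (Clipper, via
  `polyclip`, with the integer grid pinned at $10^{-10}$ px so results are
  stable to well below $10^{-9}$ under similarity transforms).

The two agree within the discretization bound set by the summed perimeters
over the raster resolution; the test suite checks this on random polygon
pairs, and checks the polygon areas themselves against a supersampled
rasterization oracle and closed-form disc geometry. ROIs are always
transformed as polygons (vertex mapping) and rasterized afterwards, never
warped as masks, so no double rasterization error enters. Intensity images,
when warped, use inverse bilinear resampling (nearest-neighbour for masks).

## Coordinate and numerical conventions

* Coordinates are 0-based, x rightward, y downward; pixel centers sit at
  integer coordinates and pixel $(0,0)$ spans $[-0.5, 0.5)^2$.
* Fill rule: even-odd, matching ImageJ composite-selection semantics;
  nesting deeper than two levels is handled by parity.
* Landmark degeneracy: estimation refuses moving-point sets whose centered
  coordinate matrix has a singular-value ratio below $10^{-6}$
  (near-collinear landmarks), raising a typed error instead of returning an
  ill-conditioned fit.
* Area of a multi-ring region: exact shoelace sums with parity signs for
  non-touching rings; when ring bounding boxes overlap the even-odd fill is
  resolved by polygon simplification first, so crossing rings (which can
  arise from heavily perturbed simulated annotations) still get the correct
  even-odd area.
* Percentiles use linear interpolation between order statistics (type 7) —
  fixed so interquartile ranges are reproducible.
* Wilcoxon signed-rank: zero differences are dropped (and counted), tied
  magnitudes get midranks, the null distribution is exact for $n \le 20$
  without ties and a normal approximation with continuity and tie
  correction otherwise. An identical pair of series yields $t = 0$,
  $p = 1$ in the paired t path rather than an error.
* The statistic choice (t vs Wilcoxon) is never auto-selected from a
  normality test; the caller chooses, with Wilcoxon the default for areas,
  so a methodological choice is never made silently.
* "Compare the median change between groups by two-way ANOVA" is internally
  tense (ANOVA compares means), so both readings are reported: the type-II
  ANOVA on raw changes and a per-label rank-based comparison.

## The synthetic scene generator

`generate_scene()` builds one eye's paired scene deterministically from a
seed; `generate_cohort()` builds a two-arm, two-visit cohort. Defaults are
the emulated study conditions:

| parameter | default | meaning |
|---|---|---|
| `frame` | 1024×1024 px over 12×12 mm | fixed OCTA grid (the cropped en-face slab covers more than a 6×6 mm scan; both are presets) |
| `n_landmarks` | 3 | landmark pairs, placed ≥ 200 px apart and non-collinear by construction |
| `true_affine` | rotation ±10°, scale 0.9–1.1, translation ±30 px | inter-modality map, drawn per scene unless supplied |
| `typeA_radius_mm` | 1.5 ± 0.2 | base radius of the star-convex type A boundary $r(\theta) = r_0(1 + \sum_k a_k \cos(k\theta + \phi_k))$ |
| `typeA_harmonics`, `typeA_harmonic_amp` | 4, 0.06 | boundary irregularity (amplitudes bounded so $r > 0$) |
| `halo_present` | 0.821 | probability of the type B halo (its reported prevalence) |
| `halo_width_mm` | 0.4 | radial width of the halo annulus |
| `n_typeC_spots`, `spot_radius_mm` | 3, 0.18 | hypo-reflective spots, strictly inside type A by construction |
| `hypo_shrink` | 0.7 | ICGA hypofluorescent spots are this radius fraction of their type C counterparts (always strictly smaller) |
| `icga_boundary_sigma_px` | 45 | boundary discrepancy between the hyperfluorescence region and the affine image of type A |
| `grader_sigma_px` | 18 | simulated grader boundary noise |
| `noise_level`, `contrast` | 0.15, 0.4 | renderer speckle amplitude and lesion/background mean contrast |

The two boundary-noise defaults were fixed once by a small Monte-Carlo
sweep so that the synthetic cohort lands in the agreement ranges reported
for this kind of data — moderate cross-modality concordance (mean JI near
0.5–0.6) and high interobserver agreement (near 0.7–0.8). With the default
lesion radius, cohort medians for the type A area fall near 7 mm² at
baseline, and type C totals near 0.3 mm², also in the reported range.

Grader simulation perturbs each ring radially with smooth,
angularly-correlated Gaussian noise (a random Fourier series with Gaussian
spectrum, correlation length 30°, including a $k{=}0$ size-bias term); the
effective sigma of a ring is capped at 30 % of its median radius so small
sharp spots are not obliterated by noise scaled to the large lesions.
Follow-up scenes rescale every lesion about the type A center by the
group's radius shrinkage factor — areas scale exactly by the square, and
ICGA regions are rescaled through the conjugated affine so cross-modality
correspondence is preserved exactly. Two RNG streams (shape vs render
noise) are derived from the master seed by fixed offsets, so appearance can
vary under identical geometry.

### What the generator does and does not emulate

It emulates the *geometry and error structure* of the measurement: lesion
taxonomy and containment relations, a true inter-modality affine, landmark
placement, boundary disagreement between modalities and between graders,
and per-group longitudinal shrinkage. The renderer only provides enough
structure for landmark detection and visual sanity — elevated speckled mean
inside type A, suppressed halo and spots, blurred fluorescence, bright
landmark crosses. It does **not** model OCTA speckle physics, fluorescence
kinetics, device segmentation artifacts, eye motion, or non-affine
distortion. Passing tests therefore demonstrate that the pipeline measures
correctly *given annotations on affinely related frames*; they cannot
certify behaviour under real-device artifacts, and the affine model itself
is an assumption inherited from the emulated procedure.

## Problem sizes used by the checks

The test suite and the acceptance script choose sizes that keep the full
run in minutes while leaving the statistics meaningful: unit and property
tests mostly use 128–512 px frames; end-to-end raster checks use the
default 1024 px frame; boundary-noise sweeps use 50 seeds per level;
statistical calibration uses 2000 replicates; longitudinal power checks use
100 replicates of a 40-eye cohort on a 512 px frame (polygon areas, and
hence relative changes, are resolution-independent). The acceptance script
simulates a 39-eye, two-visit, two-grader cohort on the default 1024 px
frame.

## Known limitations

* The JI is computed only where both annotations exist; an empty union is a
  typed error, never a silent 0 or NaN.
* Frame metadata (pixel size, field of view) is always user-supplied; the
  package never infers physical scale from image files.
* No automatic lesion segmentation, no intensity-based or nonrigid
  registration, no DICOM parsing, and no adjudication workflow between
  graders — a designated consensus annotation is accepted instead.
* Oval ImageJ ROIs are read as 72-gon approximations; curved (quad/cubic)
  composite segments are rejected with a typed error.
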