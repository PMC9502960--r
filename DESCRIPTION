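Package: octaconcord
Title: Cross-Modality Lesion Concordance for Choriocapillaris OCTA and ICGA
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Landmark-based affine co-registration of choriocapillaris
    optical coherence tomography angiography (OCTA) and indocyanine green
    angiography (ICGA) en-face frames, with region-of-interest overlap
    quantified by the Jaccard index, per-lesion-type area measurement in
    square millimetres, interobserver agreement, and baseline-to-follow-up
    area-change comparison between treatment groups. Includes a reader and
    writer for the ImageJ ROI binary format, polygon and raster overlap
    engines, and a ground-truthed synthetic paired-modality scene generator
    (type A hyper-reflective lesions, type B halos, type C spots, matched
    ICGA hyper- and hypofluorescence, landmarks, simulated graders) so the
    full pipeline is testable without clinical images.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    polyclip,
    png,
    tiff,
    jsonlite,
    car,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    sp,
    yaml
Config/testthat/edition: 3
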