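Package: tastequant
Title: Volumetric EdU Proliferation Quantification and Taste-Behavior Scoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Quantifies cell proliferation in confocal z-stacks of lingual
    organoids by per-channel normalization, 3D median and Gaussian
    denoising, contrast enhancement by grayscale erosion followed by
    morphological reconstruction, scaled-Otsu thresholding, and the
    EdU-positive to DAPI-positive voxel ratio. Also provides taste-bud
    profile morphometry (maximum projections, polygon areas,
    marker-count categorization, per-mouse summaries), behavioral scores
    for two-bottle preference and brief-access lickometer sessions,
    relative qPCR quantification by the delta-delta-Ct method, and
    ground-truthed synthetic generators for organoid stacks, lick
    sessions and Ct tables so every stage is testable without microscope
    data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    tiff,
    xml2,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
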