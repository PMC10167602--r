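Package: tauroi
Title: Group-Level and Individualized Regions of Interest for Longitudinal Tau-PET
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quantifying longitudinal change in regional tau-PET
    standardized uptake value ratios (SUVR) using group-level regions of
    interest (data-driven stages, Braak stages, temporal and whole-brain
    meta-ROIs) and five individualized ROI definitions: connectivity-based
    quartile 1, Gaussian-mixture probability intervals, voxel overlap index,
    highest tau-positive data-driven stage, and event-sequence subtype/stage
    assignment. Includes per-region two-component Gaussian-mixture positivity
    modelling, annualized change metrics and tau extent, clinical-trial
    sample-size estimation with bootstrap comparison of ROIs, and a fully
    seeded synthetic cohort generator with known ground truth for validating
    the pipeline end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    mclust,
    RNifti,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
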