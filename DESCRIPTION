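Package: sgmnet
Title: Single-Subject Gray Matter Similarity Networks and Brain Age
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Construction and analysis of single-subject similarity-based
    gray matter networks from preprocessed structural MRI volumes. Volumes
    are parcellated into 3x3x3-voxel cubes, pairwise similarity is the
    maximum Pearson correlation over the 48 lattice symmetries of a cube,
    the similarity matrix is binarized by false-discovery-rate thresholding,
    and small-world properties (normalized clustering, normalized path
    length, small-world coefficient) are estimated against degree-preserving
    randomized reference graphs. Also includes principal-component
    support-vector regression for brain-age prediction with cross-validated
    brain-predicted age difference (brain-PAD), the accompanying statistical
    stage (Mann-Whitney tests, age-by-sex interaction models in age strata,
    covariate-adjusted sex contrasts, partial correlations, comparison of
    dependent overlapping correlations, GAM age trajectories), and a
    synthetic-data generator that emulates smoothed gray matter volumes and
    cohort structure so the whole pipeline is testable without real MRI data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    igraph,
    RNifti,
    e1071,
    mgcv,
    emmeans,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
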