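Package: symplane
Title: Voxel-Based Optimal Symmetry Plane Estimation for Craniofacial Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates the mid-sagittal symmetry plane of a binary bone
    segmentation (e.g. a thresholded craniofacial CT volume) by maximizing a
    paired-voxel symmetry ratio over plane orientation and offset, yielding
    the optimal symmetry plane (OSP) and its optimal symmetry ratio (OSR).
    Also provides the two classical comparator planes (a landmark-based plane
    through crista galli, anterior nasal spine and the orbitale midpoint, and
    a surface-based plane from PCA initialization refined by mirror
    iterative-closest-point registration with rotation-only updates),
    quantitative symmetry assessments (Hausdorff distance, Jaccard and Dice
    coefficients, plane angle difference, paired Wilcoxon comparisons), a
    synthetic skull-phantom generator with exactly known ground-truth planes
    and spherical-shell protrusion perturbations, and readers/writers for
    NIfTI, NRRD, STL and landmark files.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
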