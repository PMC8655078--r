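Package: driftknn
Title: Fiducial-Free Drift Correction for Single-Molecule Localization
    Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Post-processing drift correction for single-molecule
    localization microscopy (SMLM) without fiducial markers. Estimates
    intra-dataset polynomial drift and inter-dataset constant shifts by
    minimizing a thresholded sum of nearest-neighbor distances between
    localizations, using a derivative-free simplex optimizer. Also provides
    offline 3D registration of brightfield z-stacks via normalized, whitened,
    overlap-scaled cross-correlation with sub-voxel quadratic peak fitting,
    a simulator for blinking fluorophores (uniform, star and 3D ring-pair
    emitter fields, exponential on/off kinetics, polynomial and cubic-spline
    drift curves), and an evaluation harness for drift-curve error metrics
    and parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    pracma,
    stats,
    tiff,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
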