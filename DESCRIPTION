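Package: adhesivect
Title: Micro-CT Quantification of Dental Adhesive Interface Layers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the width/thickness of the adhesive layer at the
    tooth/composite restoration interface from micro-CT voxel volumes.
    Provides synthetic three-material phantoms with known ground truth,
    three-class Otsu segmentation with morphological cleanup, an exact
    largest-inscribed-sphere local thickness transform, surface-area-versus-
    width distributions S(w) with anchor-point extraction, piecewise
    linear/parabolic S(w) models fitted under continuity constraints with
    closed-form volume integrals, and the Wilcoxon signed-rank and
    Mann-Whitney U comparisons used to contrast measurement methods and
    treatment groups.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    tiff,
    stats,
    utils,
    graphics
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
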