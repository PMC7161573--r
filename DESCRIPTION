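Package: morphovar
Title: Intraspecific Shape Variation Analysis for 3D Landmark and Linear
    Measurement Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying morphological variation within and among
    groups of specimens from 3D landmark configurations and linear
    measurements. Implements Generalised Procrustes Analysis with sliding
    semilandmarks (Procrustes-distance criterion), tangent-space and
    correlation-matrix principal component analyses, disparity metrics (sum
    of variances, median centroid distance), coefficients of variation,
    permutation Procrustes ANOVA, Pillai-trace MANOVA with per-axis ANOVAs
    and Bonferroni correction, and exhaustive specimen-subset sensitivity
    analyses. Includes readers and writers for IDAV Landmark .pts, TPS and
    CSV landmark formats, and a synthetic cochlea-like data generator with
    known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    jsonlite
Config/testthat/edition: 3
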