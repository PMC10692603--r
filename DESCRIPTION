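Package: microswarm
Title: Image-Based Motion Analysis of a Three-Species Synthetic Microbial
    Community
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and automated image-based characterization of a
    three-species synthetic microbial community (Phytophthora zoospores,
    Vorticella ciliates, enteric bacteria) responding to a potassium
    gradient in a microfluidic chamber. Provides an agent-based generator
    of 8-bit grayscale time-lapse stacks with ground truth, threshold
    binarization and connected-component spot detection with morphometrics
    (area, Crofton perimeter, circularity), size-based species
    partitioning, nearest-neighbor track linking under per-species maximal
    linking distances, per-track motion metrics (mean speed, confinement
    ratio), and grid-based microenvironment comparisons with one-way ANOVA
    and Sidak-adjusted post hoc tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    grDevices,
    graphics,
    tiff,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
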