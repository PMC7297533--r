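Package: phenoplate
Title: Quantification, Normalisation and Differential-Fitness Analysis of Arrayed Colony Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolbox for high-throughput colony-array phenomics on flatbed-scanner
    plate images. Quantifies colony size, growth curves and phloxine B viability
    (redness) scores from greyscale transmission and RGB reflective scans in
    96/384/1536 formats; extracts maximum growth slopes from image time series by
    sliding-window regression; corrects spatial plate effects with reference-grid
    surface and row/column median normalisation driven by an experimental design
    table; computes plate quality statistics (coefficient of variation, fraction of
    unexplained variance, neighbour-sum spatial bias, timepoint correlation
    matrices); and calls differential fitness between conditions with
    Benjamini-Hochberg correction. Includes a synthetic-data generator for plate
    images, growth-curve panels and multi-plate experiments with controllable
    gradients, strain effects, noise and stain-dependent colour.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
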