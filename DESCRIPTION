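Package: widefieldct
Title: Wide-Field Parallel-Beam Tomographic Microscopy Toolkit
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Plan, simulate and process wide-field synchrotron-based X-ray
    tomographic microscopy scans in which several laterally offset 180-degree
    subscans are merged into projections spanning a field of view wider than
    the detector. Provides sampling-theorem protocol planning with a
    dose/quality ladder, a Shepp-Logan phantom simulator with parallel-beam
    forward projection and flat/dark frame generation, projection
    normalization, angular interpolation, mean-squared-difference cutline
    detection and stitching, sinogram assembly, ramp-filtered backprojection,
    an Otsu-binarized slice-difference quality metric with dose-quality
    curves, and binary-volume morphometry (seeded region growing, connected
    components, Euclidean distance transform histograms).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tiff,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    EBImage,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
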