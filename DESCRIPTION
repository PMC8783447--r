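Package: guvstack
Title: Automated Confocal Z-Stack Analysis of Giant Unilamellar Vesicles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for automated analysis of confocal fluorescence z-stacks
    of giant unilamellar vesicles (GUVs) and phase-separated protein
    droplets. Sections are thresholded with the triangle method, candidate
    vesicle circles are detected with a circular Hough transform, grouped
    across z into three-dimensional vesicle entities, and quantified:
    membrane-bound fluorescence in a second channel (background-corrected
    net intensity), droplet interior intensity, and lipid phase-separation
    state from the intensity profile along the membrane contour
    (discontinuity statistic with a per-stack fraction rule). Two compact
    convolutional neural networks, trained with stochastic gradient descent
    with momentum on 50x50 patches, replace the computational vesicle
    selection filter and the phase-state decision; a built-in virtual
    confocal simulator renders ground-truth GUV scenes (spherical shells,
    domain caps, Gaussian point-spread blur, noise) to produce labeled
    training data and fully annotated synthetic stacks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
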