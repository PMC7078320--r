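Package: lvstem
Title: Dark-Field Contrast Modeling and Image Analysis for Low-Voltage STEM
    of DNA Nanostructures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models annular dark-field (DF) STEM contrast of layered
    light-element specimens with the small-angle Lenz scattering theory,
    simulates electron trajectories through three-dimensional specimen scenes
    by Monte Carlo to render DF and secondary-electron images of DNA origami
    nanostructures (with and without gold nanoparticles), generates realistic
    synthetic micrograph populations, and measures structures in micrographs:
    ROI contrast, segmentation, rectangle morphometry, contrast-ratio
    normalization, layer-number classification, line profiles, hole and
    nanoparticle detection, and population statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    grDevices,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
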