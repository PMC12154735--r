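Package: germquant
Title: Quantitative Phenotyping of Fission Yeast Spore Germination from
    Timelapse Microscopy
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to quantify spore germination in transmitted-light
    timelapse microscopy of Schizosaccharomyces pombe. Segments spores in
    each frame (or imports externally produced label masks), links objects
    into tracks, fits moment-matching ellipses to obtain calibrated area
    and aspect-ratio series, and applies rule-based scoring: aspect-ratio
    gating of circular spores, first-division calling at an aspect-ratio
    threshold, swelling-window detection, germination efficiency, and a
    five-class outgrowth phenotype taxonomy (normal, elongated, bubble,
    bipolar, exploded). Also quantifies asymmetric vacuole partitioning
    between spore body and germ tube from a second fluorescence channel,
    and implements the accompanying statistics for colony-forming-unit
    longevity curves (normalization, area-under-curve t-tests), Fisher's
    exact tests on germination fractions, one-way ANOVA on division times
    and stress-survival ratios. A synthetic timelapse generator with
    complete ground truth makes every stage testable without microscope
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    tiff,
    png,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: CellBiology, Segmentation, TimeCourse, Software
RoxygenNote: 7.3.3
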