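Package: BacFlow
Title: Label-Free Live-Cell Analysis of Bacterial Surface Colonization Under Flow
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Segmentation, lineage tracking and kinetic analysis of rod-shaped
    bacteria colonizing a surface in a microfluidic flow channel, imaged by
    brightfield time-lapse microscopy. Provides an agent-based synthetic-scene
    simulator with a brightfield renderer and ground-truth export, frame
    averaging and illumination correction, marker-controlled watershed
    segmentation with shape/size gating, footprint-overlap trajectory stitching
    with lineage, windowed single-cell growth-rate estimation with Gompertz
    population fits and transition times, surface mean-binding-time estimation
    from colonization curves, orientation/wiggle statistics that localize the
    adhesion pivot and classify rocking versus twisting binding modes, and a
    reporting pipeline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    EBImage,
    minpack.lm,
    tiff,
    jsonlite,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
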