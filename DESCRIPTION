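Package: valvemech
Title: Multi-Scale Biomechanics of Micro-Scale Planar Soft Tissues
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Analysis of miniature uniaxial stretch tests of planar soft
    tissues such as murine heart-valve leaflets. Converts elastomeric
    cantilever-post deflections to forces, builds stress-stretch curves and
    fits the exponential (Fung) constitutive law with a derived effective
    tangent modulus; quantifies cell deformation as a circularity-index
    trajectory versus stretch; quantifies matrix fiber alignment by the
    angular power distribution of the 2D Fourier spectrum; quantifies
    stained-section matrix composition as leaflet-normalized area fractions;
    and compares groups with the field's standard tests. A synthetic-data
    module generates confocal-like fiber and cell images, simulated two-post
    force records, and stained slides with known ground truth for
    validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    EBImage,
    tiff,
    yaml,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
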