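Package: memwet
Title: Membrane Fluidity and Condensate Wetting Analysis from Hyperspectral
    and Geometric Microscopy Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis chain for membrane-condensate wetting
    studies on giant unilamellar vesicles. Transforms LAURDAN hyperspectral
    image stacks into spectral phasor coordinates, classifies pixels with
    circular cursors, and summarises lipid packing as a fluidity fraction
    with its histogram center of mass. Fits circles to the three interface
    arcs of a vesicle-condensate cross-section and extracts apparent contact
    angles, the geometric factor, the intrinsic contact angle, the affinity
    contrast, and the membrane segment tensions from the tension triangle.
    Converts condensate drift under a DC electric field into a zeta
    potential with a modified Smoluchowski relation for liquid droplets.
    Ships seeded synthetic-data generators for every stage so each estimator
    is verifiable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
Suggests:
    EBImage,
    minpack.lm,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
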