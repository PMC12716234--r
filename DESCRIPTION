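Package: guvmech
Title: Membrane Area Expansion Modulus of Giant Unilamellar Vesicles from
    Deformability Cytometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Extracts the membrane area expansion modulus K of giant
    unilamellar vesicles (GUVs) from real-time deformability cytometry (RT-DC)
    event data. Implements a simulation-calibrated power-law response surface
    for per-vesicle (direct) fitting, a noise-resistant collective estimator
    based on the slope of the deformation-area relation, and a combined
    pipeline that removes outlier events with a Gaussian mixture model on the
    log-modulus before collective refitting. All estimators are formulated on
    nondimensional quantities so that results transfer across flow rates,
    channel sizes and buffer viscosities. Includes contour-based shape
    features (deformation, porosity) with pixelation correction and quality
    gates, a synthetic event generator with a lognormal noise model for
    offline validation, CSV/TSV readers and writers for RT-DC style event
    tables, and a command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    grDevices,
    jsonlite,
    minpack.lm,
    stats,
    tools,
    utils
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
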