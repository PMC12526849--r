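Package: cornfit
Title: Three-Surface Corneal Model Fitting and Repeatability Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fits floating spherocylinder, cylindrical-conoid and biconic
    model surfaces to polar height maps of the corneal epithelium,
    epithelium-stroma interface and endothelium as exported by
    anterior-segment OCT tomographers, converts the fitted geometry to
    dioptric power vectors (SEQ, C0, C45) and layer thicknesses, and
    quantifies measurement repeatability with nonparametric bivariate
    statistics (Henze-Zirkler normality test, medoids, convex-hull-peeling
    confidence regions, double-angle summaries).  A synthetic-cornea
    generator produces cohorts of height-map measurements with realistic
    population structure so the whole pipeline can be exercised and
    validated without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    grDevices,
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
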