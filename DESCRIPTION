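Package: discHb
Title: Optic Disc Hemoglobin Colorimetry from Color Fundus Photographs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates the relative hemoglobin (Hb) content of optic nerve
    head tissue from ordinary RGB fundus photographs. The pipeline gates
    image quality, delimits the disc semi-automatically, identifies the
    central retinal vessels, uses the vessels as an internal 100 percent Hb
    reference to convert tissue color into per-pixel Hb percentages with
    compensation for crystalline-lens yellowing, and aggregates the map over
    24 papillary sectors (eight 45-degree wedges by three concentric rings).
    Cohort-level tools compare groups with pooled-variance t-tests under
    Bonferroni correction and compute Pearson correlations against retinal
    nerve fiber layer thickness tables. A synthetic fundus-image and cohort
    generator with full ground truth supports validation end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    EBImage,
    png,
    tiff,
    nortest,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
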