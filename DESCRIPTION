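Package: octvessel
Title: Retinal Vessel Wall Morphometry from OCT Cross-Sections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Measures retinal small-vessel wall morphology on optical
    coherence tomography (OCT) cross-section images. Provides synthetic
    vessel phantom and three-group cohort generators with known ground
    truth, the standard OCT preprocessing chain (512x512 standardization,
    contrast-limited adaptive histogram equalization, Canny edge map,
    region-of-interest extraction), a fully automatic full-width-at-
    half-maximum (FWHM) edge detector that locates the four vessel-wall
    boundaries along candidate pixel columns, computation of the eleven
    vessel-wall parameters (outer and lumen diameters, wall thickness,
    wall-to-lumen ratio, wall cross-sectional area, arteriovenous ratio),
    and the three-group comparison (one-way ANOVA with a Levene gate
    selecting LSD or Games-Howell post hoc tests).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    car,
    igraph,
    jsonlite,
    png,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
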