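Package: mpstruct
Title: Point-to-Point Structure-Function Analysis of Drusen, Hyperreflective
    Foci and Microperimetric Retinal Sensitivity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis pipeline for point-to-point
    structure-function correlation in non-exudative age-related macular
    degeneration. Generates seedable synthetic cohorts of eyes with drusen
    and hyperreflective-foci (HRF) en-face thickness fields evolving over
    quarterly visits, simulates 4-2-1 staircase microperimetry at a
    45-point high-density stimulus grid, registers the fundus-photo frame
    to the OCT en-face raster by landmark least-squares affine estimation,
    aggregates lesion volumes in circular regions of interest around each
    stimulus, and fits nested linear mixed models (spot within eye within
    patient) relating retinal sensitivity to local drusen and HRF load,
    visit (learning effect) and eccentricity.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    lme4,
    jsonlite,
    stats,
    utils,
    tiff
Suggests:
    testthat (>= 3.0.0),
    emmeans,
    yaml,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
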