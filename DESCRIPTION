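Package: woodscreen
Title: Screening Woody Plants for Sequential Drought-Heat Stress Tolerance
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An integrated analysis pipeline for pre-screening woody plant
    species for tolerance to sequential drought and heat stress.  Implements
    the closed-form physiological stress indices (relative water content,
    electrolyte leakage and its heat-stress index, the Evans-blue inhibition
    index, survival rate), a reproducible quantification algorithm for
    DAB-stained leaf images (inverted red-channel stain scoring, automatic
    placement of square regions of interest on the most stained zones,
    background correction, HSV-saturation readout), a standardized-score
    quadrant classifier that pre-selects tolerance candidates from (RWC, ELI)
    scatter, recovery-kinetics summaries of hydrogen-peroxide time series
    across a 14-phase stress/recovery schedule, one-way ANOVA with Duncan's
    multiple range test and compact letter displays, and synthetic-data
    generators with known ground truth for every input class.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    png,
    tiff,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
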