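Package: synletscreen
Title: Bliss Synergy Analysis for Genotype-Differential Drug Combination Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for plate-based drug combination screens in
    isogenic cell-line panels: normalization of viability reads to vehicle
    controls, Bliss-independence delta-score matrices and scalar synergy
    scores for 6x6 dose matrices, genotype-differential hit ranking across a
    compound panel, four-parameter logistic single-agent IC50 fitting,
    high-content quantification of nuclear gammaH2AX foci (background
    correction, nucleus segmentation with shape/intensity filters,
    box-method spot detection), and in-vivo tumor growth endpoints (caliper
    volume, relative tumor volume, progression-free survival with
    Kaplan-Meier and log-rank comparison). Ships seeded synthetic-data
    generators for every input type so the full pipeline is testable
    without raw screen data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    minpack.lm,
    survival,
    EBImage,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
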