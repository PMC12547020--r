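Package: gpcrtraffic
Title: Quantification of Yeast GPCR Trafficking Phenotypes from Fluorescence
    Microscopy
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantification and statistics pipeline for studies of yeast
    mating-receptor (GPCR) trafficking. Measures peripheral plasma-membrane
    receptor abundance from fluorescence images and label masks (morphological
    ring masks with pseudo-flat-field background subtraction), classifies
    vacuoles as cargo-full or cargo-empty from two-channel line scans
    (rolling-ball background subtraction, two-peak lumen:membrane ratio),
    fits Hill dose-response curves with confidence-interval overlap tests,
    assigns rescue categories from ANOVA/Tukey comparisons, and computes
    quantitative mating efficiencies. A synthetic-data module generates
    imaged fields, line profiles, dose-response plates and colony counts with
    known ground truth so that every pipeline stage is testable by parameter
    recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    EBImage,
    tiff,
    png,
    minpack.lm,
    withr,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
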