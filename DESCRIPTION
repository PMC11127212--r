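Package: ims4d
Title: Four-Dimensional Metabolite Annotation for Traveling-Wave Ion
    Mobility Mass Spectrometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for annotating small-molecule features from ion
    mobility-mass spectrometry experiments against four-dimensional
    reference libraries (m/z, retention time, collision cross-section and
    MS/MS fragment spectra). Includes traveling-wave CCS calibration with
    single-point lock-CCS correction, chemical-formula arithmetic
    (monoisotopic mass, isotope patterns, adduct m/z), tolerance-based
    candidate filtering with composite scoring and Metabolomics Standards
    Initiative confidence levels, quality-control analytics (inter-day
    %RSD, accuracy versus reference CCS sets, matrix effects, per-class
    m/z-CCS power trendlines, adduct CCS shifts), seeded synthetic-data
    generators, and a packaged reference library of 55 level-1 urinary
    metabolites measured on a UPLC/TWIMS-QTOF platform.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
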