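Package: posE13C
Title: Carbon-Position-Resolved 13C Enrichment Analysis of Aspartate by GC-MS
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Determines fractional 13C enrichment (E13C) at each carbon
    position of aspartate from GC-MS in-source fragment ions. Extracts mass
    isotopologue distributions (MIDs) from high-resolution GC-APCI-MS
    chromatograms (mzML) or nominal-mass GC-EI-MS peak tables, corrects them
    for natural isotope abundance by molecular formula, combines fragment
    enrichments covering carbon subsets 1,2,3,4-C, 2,3,4-C, 2,3-C and 3,4-C
    into per-position enrichments with propagated uncertainties, converts
    enrichments to molar 13C concentrations via internal-standard calibrated
    quantification, and estimates maximal carbon-assimilation rates by
    sigmoidal time-course fitting. Ships a standards-mixture validation
    engine (accuracy, precision, detection limits, detector-saturation
    flagging) and a synthetic-data generator that emulates isotopologue
    envelopes of silylated aspartic acid fragments for arbitrary positional
    labeling, standard-mixture panels and day/night 13CO2 pulse-labeling
    time courses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    pracma,
    minpack.lm,
    mzR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
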