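Package: mucomics
Title: Comparative Mechanics, Glycomics and Composition of Mucus Secretions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.com")
Description: Tools for comparative ("mucomic") analysis of mucus hydrogels,
    built around four stages exercised end-to-end on synthetic data with known
    ground truth: Johnson-Kendall-Roberts (JKR) contact-mechanics analysis of
    AFM nanoindentation force curves (Young's modulus and work of adhesion),
    composition annotation of permethylated-glycan MALDI-TOF peak lists with
    native-methylation inference from paired CH3/CD3 permethylation runs,
    normalization of energy-dispersive X-ray (EDX) element abundances into
    weight-percent profiles, and identification filtering plus spectral-count
    functional profiling of proteomic tables. A synthetic-data module generates
    every input the pipeline consumes, so each stage is testable by parameter
    recovery.
License: MIT
Encoding: UTF-8
Imports:
    graphics,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    signal,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
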