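Package: abivr
Title: Antibiotic-History Instrumental-Variable Regression for Microbiome-Disease Causal Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates causal effects of a gut-microbiome summary exposure
    (the log Prevotella/Bacteroides ratio) on incident diseases using
    long-term antibiotic prescription history as an instrumental variable in
    a two-sample two-stage least-squares design. Builds the instrument and
    incident-disease outcomes from EHR-style prescription, diagnosis and
    subject tables (10-year exposure window, 6-month washout, ATC J01*
    antibiotic classes), computes the log Prevotella/Bacteroides ratio from
    genus-level relative abundances with a half-minimum pseudocount, fits
    the two-stage ratio-of-coefficients estimator with a delta-method
    standard error and Benjamini-Hochberg false-discovery-rate control, and
    provides a pseudo-outcome null-calibration and sensitivity-scenario
    suite together with a synthetic two-sample biobank generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml,
    optparse
Config/testthat/edition: 3
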