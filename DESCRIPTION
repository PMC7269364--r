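Package: muacdose
Title: MUAC-Based Energy Dosing Analysis for Acute Malnutrition Programs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for designing and evaluating simplified mid-upper arm
    circumference (MUAC) based dosing protocols for the outpatient treatment
    of child acute malnutrition. Provides a synthetic generator for
    longitudinal feeding-program patient cards, usability and biological
    plausibility filters, LMS growth-reference z-scores,
    interval-normalized growth velocities with local polynomial kernel
    smoothing, a normalized-difference trend test with country-stratified
    resampling, per-visit energy-needs estimation from maintenance and
    tissue-deposition constants, band-wise percentile dosage derivation,
    and a resampling simulation comparing the energy coverage of candidate
    dosing protocols.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    graphics,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
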