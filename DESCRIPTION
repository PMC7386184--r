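Package: rtverify
Title: Independent Calculation-Based Verification of Radiotherapy Dose
    Distributions
Version: 0.1.0
Authors@R:
    person("RT", "Verify Developers", email = "rtverify@example.org",
           role = c("aut", "cre"))
Description: Tools for patient-specific quality assurance of
    volumetric-modulated arc therapy (VMAT) and stereotactic body
    radiotherapy (SBRT) plans by independent recalculation.  Provides 3-D
    dose-grid and structure handling (rasterization, isotropic margin
    expansion, trilinear resampling), dose-difference and gamma-index
    comparison of paired dose distributions with passing rates under the
    10 percent isodose threshold, Simpson's Faunal Resemblance Index over
    fail-point sets, dose-volume histogram construction with dosimetric
    and volumetric error metrics and tolerance levels, seeded synthetic
    phantom and patient-geometry generators, and an orchestration layer
    producing cohort report tables.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
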