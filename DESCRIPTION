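Package: sirteq
Title: Radiobiological Equivalence of Y-90 Radioembolisation and
    External-Beam Radiotherapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for the radiobiological analysis of protracted
    yttrium-90 beta-particle irradiation of cell monolayers relative to
    acute external-beam exposure. Computes evaporation-corrected
    cumulated absorbed dose for a decaying Y-90 source with a linearly
    drifting S-value, fits the linear-quadratic survival model to
    clonogenic assay counts as a random-intercept mixed model by
    restricted maximum likelihood with delta-method alpha/beta standard
    errors and Wald tests, evaluates the Lea-Catcheside dose-protraction
    factor for finite and fully-decayed exposures, inverts it for the
    sublethal-damage repair half-time, and converts Y-90 absorbed dose
    to biologically effective dose (BED) and equivalent fractionated
    external-beam dose (EQD2/EQD10). Includes a clonogenic-assay
    simulator with Poisson colony counts, plating efficiency and
    replicate-level random effects for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    yaml
Suggests:
    testthat (>= 3.0.0),
    nlme,
    jsonlite
Config/testthat/edition: 3
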