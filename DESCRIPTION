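Package: scalafit
Title: Template-Based Scalar Localization of Cochlear-Implant Electrode Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Determines the scalar position (scala tympani, intermediate, or
    scala vestibuli) of each contact of a cochlear-implant electrode array by
    registering a basilar-membrane mid-surface template to the implanted
    cochlea through four anatomical landmarks. Provides cochlear morphometry
    (distances A, B, H360 and the derived indices), construction and selection
    of a five-template bank spanning the population distribution of the
    (A/B) x H360 index, landmark-based similarity registration, point-cloud to
    surface distances, threshold-based per-electrode classification using a
    spherical-cap coverage fraction, and multi-rater agreement statistics
    (Fleiss' kappa with bootstrap intervals, chi-squared proportion tests).
    A parametric cochlear-spiral simulator generates synthetic cochleae and
    implanted arrays with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
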