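Package: raidose
Title: Lesion Dosimetry and Theranostic Dose Prediction for Radioiodine Therapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative-imaging dosimetry analysis for radioiodine (I-123 /
    I-131) therapy of iodine-avid lesions. Fits mono-exponential time-activity
    curves to serial lesion activity measurements, computes lesion self-dose
    absorbed doses under the MIRD formalism with mass-adjusted S values and
    propagated standard uncertainties, converts diagnostic I-123 kinetics into
    predicted therapeutic I-131 uptake and absorbed dose, applies an
    uptake-increase eligibility gate and per-lesion RECIST response
    classification, and provides the agreement statistics used to compare
    predicted with delivered doses (group-mean-centered correlations,
    Bland-Altman analysis, Kruskal-Wallis test, intraclass correlation).
    Includes a hierarchical lognormal synthetic cohort generator so that the
    whole pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    minpack.lm,
    optparse
Config/testthat/edition: 3
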