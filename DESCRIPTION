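Package: crvtoffset
Title: Central Retinal Vascular Trunk Offset Morphometry and Paired-Eye Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Geometric measurement of central retinal vascular trunk (CRVT)
    deviation from the Bruch's membrane opening (BMO) centre on delineated
    OCT landmarks (the dimensionless offset index a/b and the angular
    deviation in right-eye orientation), together with the paired-eye
    inference chain used in unilateral normal-tension glaucoma studies:
    paired comparisons, matched-pair conditional logistic modelling with
    univariable screening, linear generalized estimating equations with
    cubic axial-length terms and exchangeable within-pair correlation,
    LOESS smoothing, closed-form cubic minimisation, and angle
    correlations. A calibrated synthetic paired-eye cohort generator
    reproduces the reference cohort's group distributions, generative
    cubic, within-pair correlation structure and exclusion cascade so the
    whole pipeline runs with no patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    survival,
    tibble
Suggests:
    testthat (>= 3.0.0),
    nlme,
    optparse,
    withr
Config/testthat/edition: 3
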