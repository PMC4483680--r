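Package: pcdosim
Title: Sparse Polynomial Chaos Surrogates for Magnetic-Field Orientation
    Dosimetry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Stochastic dosimetry toolkit for assessing how the orientation
    of a uniform 50 Hz magnetic flux density influences the induced electric
    field in fetal tissues.  Builds sparse polynomial chaos expansions of the
    tissue-wise 99th-percentile induced field over the two spherical
    orientation angles (orthonormal Legendre basis, least-angle-regression
    term selection, leave-one-out model choice, relative mean-square
    validation error), and post-processes them into exposure statistics:
    analytic moments and coefficient of variation, worst-case maxima against
    ICNIRP 2010 basic restrictions, and high-exposure orientation regions
    with Monte-Carlo solid angles.  A closed-form quasi-static eddy-current
    solver for a homogeneous triaxial ellipsoid supplies synthetic
    observations with the structure the analysis assumes; users with their
    own deterministic solver can supply observation tables instead.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
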