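Package: domaincut
Title: Protein Domain Boundary Prediction from Residue Contact Maps
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Predicts protein domain boundaries from ranked residue-residue
    contact lists by Gaussian kernel density smoothing of a contact-cut
    profile, with several bandwidth-selection schemes (fixed, linear,
    logarithmic, power-law and AMISE plug-in). Includes two baseline
    predictors (a Bayesian chain-length model and a homology
    alignment-endpoint profile method), derivation of contacts from
    C-alpha-only structures via pseudo-C-beta geometry, the normalized
    domain overlap (NDO) assessment score with stable-marriage label
    matching, and seeded synthetic-data generators for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    bio3d
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
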