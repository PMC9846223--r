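Package: gsempath
Title: Recursive Generalized Structural Equation Path Analysis and
    Mediation for Neonatal Care-Seeking Surveys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits a recursive system of link-scale regression equations
    (a generalized structural equation model without latent variables)
    over a hypothesized directed acyclic graph of survey variables, and
    decomposes each exposure's effect on a binary outcome into direct,
    path-specific indirect, total indirect, and total effects on the
    log-odds scale by the product-of-coefficients method, with
    delta-method confidence intervals, robust (sandwich) standard
    errors, mediation proportions, and average relative effects for
    multi-categorical exposures. Ships the six-equation care-seeking
    diagram for sick newborns in rural Bangladesh together with the
    published adjusted odds ratios as a packaged fixture, and a
    cluster-survey simulator that generates record-level data with that
    coefficient structure as ground truth, so the whole pipeline is
    testable without access to the restricted survey records.
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
    igraph,
    MASS,
    sandwich,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
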