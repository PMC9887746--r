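Package: crisisseverity
Title: Latent-Variable Modelling of Humanitarian Crisis Severity Indices
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for building and re-examining composite humanitarian
    crisis-severity indices of the INFORM/GCSI family. Computes the original
    three-pillar index (weighted means, geometric means, and the 5-percent
    population-conditions rule) from sub-indicator inputs, and re-models the
    crisis-by-indicator table as a latent-variable system: indicator
    screening by missingness, maximum-likelihood exploratory factor analysis
    with direct-quartimin (oblimin) rotation and explicit factor-retention
    and indicator-pruning rules, full-information maximum-likelihood
    confirmatory factor analysis (first- and second-order) with
    residual-driven model modification, chi-square/CFI/TLI/RMSEA fit
    indices, and normalized latent severity scores. Includes a synthetic
    crisis-table generator with known second-order latent structure for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    readxl,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
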