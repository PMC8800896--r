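Package: npirt
Title: Nonparametric Item Response Theory Scaling for Ordinal Questionnaires
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Polytomous Mokken scale analysis for ordinal questionnaire data
    such as the EQ-5D-5L health profile. Implements Loevinger scalability
    coefficients (pairwise, item and scale level) with bootstrap standard
    errors, the automated item selection procedure with lower-bound sweeps,
    manifest monotonicity checks over rest-score groups, manifest invariant
    item ordering with backward selection and the HT coefficient, and the
    Guttman lambda-2 and Molenaar-Sijtsma rho reliability estimates. A graded
    response model generator produces ordinal data satisfying the monotone
    homogeneity model (with controllable violations) for testing and for
    emulating the EQ-5D-5L level sum score analysis on synthetic samples.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    data.table,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'AllClasses.R'
    'AllGenerics.R'
    'response-matrix.R'
    'profiles.R'
    'io.R'
    'scalability.R'
    'item-selection.R'
    'monotonicity.R'
    'item-ordering.R'
    'reliability.R'
    'synthetic-data.R'
    'pipeline.R'
    'plots.R'
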