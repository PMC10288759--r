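Package: circguide
Title: Design and Screening of Circular Guide RNA Expression Cassettes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for designing circular guide RNA (cgRNA) expression
    cassettes for Cas12a and CasRx. Assembles Tornado-style cassettes in
    which the guide is flanked by Twister ribozymes and ligation sequences
    so that autocatalytic cleavage and RtcB ligation yield a circular guide
    in cells. Provides deterministic RNA secondary-structure prediction
    (a bundled nearest-neighbour energy model and a Nussinov maximum-pair
    engine, both supporting circular folding, plus an adapter for an
    external ViennaRNA RNAfold binary), a digital linker-library screen
    that folds candidate precursors, filters them by scaffold and ribozyme
    motif integrity, ranks them by predicted free energy and groups them by
    structural similarity, and the editing-outcome statistics used to
    evaluate such guides (specificity index, FACS cleavage efficiency,
    fold-change normalisation and decay half-life estimation).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    Biostrings,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml,
    rlang,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'parts.R'
    'assemble.R'
    'folding.R'
    'vienna.R'
    'screening.R'
    'fixtures.R'
    'quantify.R'
    'io.R'
    'cli.R'
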