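Package: isletdep
Title: Reference-Anchored Differential Proteome Analysis for Stem-Cell-Derived Islet Cells
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Differential-expression and regulation-classification pipeline for
    quantitative (TMT-style) proteomics of human induced pluripotent stem cells
    differentiating towards pancreatic islet cells, with native islets as the
    reference. Calls differentially expressed proteins between cell populations
    and islets by fold change and Student's t-test, classifies each protein's
    response to defined culture effects (differentiation cocktail,
    encapsulation at early or late stages, and their confounding combination)
    as islet-promoting, islet-antagonizing or unchanged, flags attainment of
    islet-like abundance, partitions islet-promoting sets across effects,
    performs hypergeometric over-representation tests and protein-transcript
    direction concordance, and clusters samples with squared-Euclidean Ward
    linkage. A synthetic-data generator plants known regulation classes so the
    whole chain is verifiable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
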