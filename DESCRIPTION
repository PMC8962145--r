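Package: MolPairGen
Title: Molecular Pair Mining and Property-Conditioned SMILES Generation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Mines molecular-pair training sets from publication-grouped
    compound collections under matched-molecular-pair, Tanimoto-similarity
    and scaffold-matching criteria, encodes ADMET property changes (logD,
    solubility, clearance) as discrete conditioning tokens, trains a
    sequence-to-sequence transformer on SMILES pairs conditioned on the
    requested property change, and evaluates generated molecules against
    error-adjusted property bands and criterion-specific structure
    constraints. Includes a synthetic corpus generator with an enumerable
    structure-to-property grammar so the full pipeline runs at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    graphics,
    ChemmineOB,
    igraph,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
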