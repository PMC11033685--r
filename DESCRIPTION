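Package: polyspec
Title: Polyspecificity Prediction from Antibody VH Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Sequence-based prediction of antibody polyspecificity from
    aligned heavy-chain variable-region (VH) sequences. Implements a
    physico-chemical feature encoding (PCA compression of an AAindex-style
    amino-acid property table with positional flattening), a small fully
    connected neural classifier trained with class-balanced minibatches,
    random and group-blocked cross-validation with explicit elimination of
    train/validation sequence overlaps, permutation-based feature importance
    (dropout loss ratio) with nonparametric p-values and Benjamini-Hochberg
    FDR, and back-calculation of importance onto the raw physico-chemical
    properties. A seeded synthetic repertoire generator with planted,
    tunable class-dependent property shifts makes the whole pipeline
    testable without access to real immunization data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3), methods
Imports: stats, utils, tools, seqinr, jsonlite, yaml
Suggests: testthat (>= 3.0.0), pROC, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
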