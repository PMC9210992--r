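Package: arrma
Title: Assumed Reciprocity, Reciprocity, and Metaperception Accuracy in
    Dyadic Designs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Social Relations Model (SRM) decomposition of multi-interaction
    dyadic data (round-robin, asymmetric-block, and half-block designs) into
    actor, partner, and relationship effects, and simultaneous estimation of
    assumed reciprocity, reciprocity, and metaperception accuracy (ARRMA) at
    the individual and dyadic levels.  Includes minimal and full dyadic models
    for distinguishable and indistinguishable dyads with Olsen-Kenny equality
    constraints and I-SAT chi-square adjustment, a generic maximum-likelihood
    covariance-and-mean-structure engine with labeled equality constraints, a
    synthetic-data generator with known truth for parameter-recovery studies,
    CSV/YAML/JSON interfaces, and a command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    pracma
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
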