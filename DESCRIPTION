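Package: loopscreen
Title: Loop-Based Virtual Screening of Small Molecules Targeting
    miRNA-mRNA Interactions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for nominating small molecules that target the loops
    formed during Argonaute-mediated miRNA-mRNA interactions. The package
    folds joined miRNA-mRNA sequences under a loop-additive energy model
    with a constrained dynamic program, detects and profiles loops,
    predicts target sites with a seed-constrained weighted alignment,
    computes accessibility-corrected interaction energies from unpaired
    probabilities, builds 1250-dimensional interaction feature vectors
    (226 RNA features joined with 1024-bit circular molecule
    fingerprints), trains and applies a knowledge-based classifier,
    parses docking logs for structure-based scores, and combines both
    rankings into a consensus candidate list. A synthetic-data module
    generates every input the pipeline consumes so the full system is
    testable offline.
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
    ChemmineOB,
    ranger,
    MASS,
    class,
    rpart,
    e1071,
    glmnet,
    pROC,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
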