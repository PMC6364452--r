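Package: smtr
Title: Stochastic Modelling and Mutation-History Estimation for Tandem
    Repeats
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Models the formation of tandem repeat sequences by tandem
    duplication and substitution mutations on a circular DNA sequence.
    Provides the generative simulator, the autocorrelation rate matrix of
    the associated ordinary differential equation limit together with its
    stationary profiles and null spaces, and the SMTR inverse estimator,
    which recovers conditional mutation probabilities and the total
    mutation count from a single observed repeat sequence by constrained
    least squares on the circular autocorrelation profile. Includes
    readers for FASTA and Tandem Repeats Finder catalogs with the
    preprocessing filters used for genome-scale repeat analysis, and a
    simulation harness for parameter-recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    utils,
    quadprog,
    Matrix,
    Biostrings,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
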