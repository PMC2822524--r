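Package: plan7
Title: Profile Hidden Markov Models for DNA Repeat Families
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and trains Plan 7 profile hidden Markov models for DNA
    sequence families such as transposable elements. Implements Baum-Welch
    together with two training variants designed to escape the local optima
    that plague EM on four-letter alphabets: Conditional Baum-Welch, an
    expectation conditional maximization scheme that updates one model
    position at a time using a banded, state-major dynamic programming
    recursion, and Dynamic Model Surgery, which inserts and removes model
    positions during training when expected insertion or deletion usage
    crosses a threshold. Includes a simulation harness that generates truth
    profiles at a stated conservation level and samples sequence sets from
    them, a local-mode Viterbi scanner with shuffle-calibrated score
    thresholds for hit calling, and a transitive-alignment metric that scores
    hits on two genomes against each other through a genome-genome fragment
    alignment map.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
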