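Package: vireosyntax
Title: Variable-Order Markov Models of Birdsong Syntax
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for analysing the syntax of symbolic vocal sequences such as
    the phrase sequences of Cassin's Vireo song. Fits zero-, first- and
    second-order Markov models to annotated recording corpora, smooths them by
    Witten-Bell discounting with recursive backoff, builds mixed-order
    "interpolated" models by greedy forward selection against held-out
    likelihood, screens for second- and third-order dependencies with Fisher's
    exact tests under Bonferroni control, compares models to data through
    N-gram and recurrence-interval distributions and their L1 distances, tests
    time homogeneity of transition probabilities by parametric simulation, and
    measures next-phrase predictability overall and stratified by singing
    rate. Includes Praat TextGrid input/output and a synthetic ground-truth
    corpus generator for validation studies.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
LinkingTo:
    Rcpp
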