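Package: picrf
Title: Precursor-Induced Conditional Random Fields for Clinical Named
    Entity Recognition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Linear-chain conditional random fields (CRFs) for named
    entity recognition in clinical text, including a precursor-induced
    CRF whose non-entity states remember the class of the most recent
    preceding entity.  Outside labels are rewritten by a deterministic
    label-induction transform so that first-order transitions carry
    long-distance entity-to-entity dependencies, and observation symbols
    are shared across all outside states to avoid the sparsity the
    induction would otherwise create.  Includes first- and second-order
    CRF baselines, L-BFGS training with l2 regularization, exact
    forward-backward and Viterbi inference, CoNLL-style corpus input and
    output, entity-level precision/recall/F1 evaluation on whole and
    multi-entity sentences, inter-entity distance profiling, and a
    synthetic clinical-corpus generator with controlled entity-transition
    structure for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    yaml,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
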