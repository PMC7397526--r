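Package: retreat
Title: Discriminative Learning of Causative Alternations
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling how language learners restrict causative
    generalizations ("retreat from overgeneralization"). Implements corpus-derived
    entrenchment and preemption predictors as signed chi-square statistics over
    verb-by-construction contingency tables, aggregation of multi-rater verb
    semantics into standardized predictors and unit-interval model inputs, a
    single-layer discriminative network (Widrow-Hoff delta rule with softmax
    outputs) trained on corpus-sampled utterances with ensemble runs and
    split-half generalization to unseen verbs, by-verb correlation evaluation
    against graded grammaticality judgments, and a synthetic-data generator
    (Zipfian corpora, rater tables, judgment tables) so the whole pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    graphics,
    utils,
    tools,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
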