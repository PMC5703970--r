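Package: herbSynergy
Title: Network-Pharmacology Screening of Synergistic Compound Combinations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: An in-silico screen for synergistic drug combinations from a
    herbal compound library. Implements continuous-Tanimoto drug-likeness
    filtering against a reference drug-library profile, ensemble
    (random-forest/support-vector) interaction-score thresholding with
    organism normalization and disease mapping, hypergeometric
    over-representation analysis of target sets, bipartite compound-target
    and tripartite compound-target-pathway network construction with degree
    and hub statistics and SIF/GraphML/TSV export, and a Probability
    Ensemble Approach synergy scorer: binned likelihood-ratio naive Bayes
    over pair-similarity features returning a synergy probability, with
    AUC evaluation and top-k ranking. Ships a synthetic-data generator that
    plants each stage's signal so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    xml2,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
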