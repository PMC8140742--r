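Package: pepBench
Title: Peptide Sequence Encodings and Encoding Benchmarking
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Sequence-based peptide encodings (composition, gapped-pair,
    sliding-window, autocorrelation, CTD, conjoint triad, sequence-order,
    pseudo amino-acid composition, reduced-alphabet k-tuples, per-residue,
    chaos-game representation and related descriptor families) as pure
    functions from labelled peptide datasets to numeric feature matrices,
    together with the infrastructure to benchmark them: parameter-grid
    expansion with redundancy filtering, a tertiary-structure approximation
    step that clips template structures found by a pluggable sequence
    search, a repeated stratified cross-validation harness with a pluggable
    probabilistic classifier, and a statistical comparison layer covering
    performance metrics, classifier similarity, Friedman/Nemenyi
    critical-difference analysis, adjusted RV matrix correlation,
    Davies-Bouldin class separation and cross-dataset group ranking with
    UPGMA clustering. A synthetic two-class dataset generator provides
    reproducible fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    jsonlite,
    randomForest,
    bio3d,
    ape
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
biocViews: Classification, FeatureExtraction, Proteomics
RoxygenNote: 7.3.3
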