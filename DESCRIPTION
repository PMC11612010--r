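Package: epimstate
Title: Microstate, Complexity and Spectral Characterization of Preictal EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Characterizes interictal and preictal scalp EEG from three
    complementary perspectives: microstate temporal dynamics (global field
    power, topographic atomize & agglomerate hierarchical clustering,
    backfitting, duration/coverage/occurrence), nonlinear complexity of both
    the voltage signal and the microstate symbol sequence (Lempel-Ziv
    complexity, permutation entropy, and microstate-based counterparts mLZC
    and mPermEn), and absolute band power with the theta/beta ratio. Includes
    an EDF reader/writer, a preprocessing chain for 10-20 scalp montages, a
    synthetic EEG generator with planted microstate structure, a repeated
    cross-validated SVM prediction protocol with seizure-prediction metrics,
    and paired statistical comparisons with effect sizes.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    signal,
    e1071,
    pROC,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'RcppExports.R'
    'epimstate-package.R'
    'classes.R'
    'complexity.R'
    'edf.R'
    'features.R'
    'io-export.R'
    'microstate.R'
    'positions.R'
    'prediction.R'
    'preprocess.R'
    'spectral.R'
    'statistics.R'
    'synthetic.R'
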