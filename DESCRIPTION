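Package: omicfs
Title: Supervised Feature Selection and Benchmarking for Multi-Omics Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for selecting small, non-redundant feature subsets from
    high-dimensional multi-omics profiles (expression, methylation, copy
    number, pathway activity) with per-sample class labels, and for
    benchmarking competing selectors on equal footing. Implements greedy
    forward selection under six mutual-information criteria (MIFS, MIFS-U,
    mRMR, NMIFS, INMIFS, VWMRmR), sparse-LDA discriminative feature
    selection (l2,p-regularized), and SVM-RFE with correlation bias
    reduction. Selections are scored by repeated stratified cross-validation
    accuracy under four classifiers, redundancy rate under two similarity
    measures, and representation entropy, and compared by cross-method
    signature intersection. Includes a seeded synthetic multi-omics
    generator with planted ground truth and an end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    class,
    e1071,
    rpart,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    limma,
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
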