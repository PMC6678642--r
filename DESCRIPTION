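Package: molgcn
Title: Molecular Graph Convolutional Networks for ADME Property Regression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Graph convolutional neural networks for predicting ADME
    (absorption, distribution, metabolism, excretion) and related molecular
    properties from 3D structures. Molecules are featurized as atom and
    atom-pair feature graphs, transformed by stacked shared-weight convolution
    filters with commutative Max/Sum/Avg reduction, pooled to a fixed-length
    molecule embedding and regressed through a dense head, optionally for
    several assay endpoints jointly with masked multi-task losses. Includes
    model selection plus an order-invariant ensemble fine-tuning stage,
    chronological train/test splitting, assay-value cleaning, circular
    fingerprints with Tanimoto similarity confidence scoring, and a
    deterministic generator of synthetic drug-like molecules with additive
    atomic property labels for end-to-end testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    methods,
    jsonlite,
    yaml,
    ChemmineR
Suggests:
    testthat (>= 3.0.0),
    withr,
    ChemmineOB,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
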