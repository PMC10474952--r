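Package: drpfuse
Title: Multi-Source Similarity Fusion for Drug Response Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts drug sensitivity (IC50) of cancer cell lines from
    multi-source drug and cell-line data. Builds twelve drug similarity views
    (six molecular fingerprints, four biological-entity association profiles,
    chemical-chemical combined scores, and IC50 response profiles) and four
    cell-line feature views (expression, mutation, copy number, response-profile
    similarity) using row-wise Chebyshev distance; completes sparse association
    views and fuses views with similarity network fusion (SNF); and fits a
    neural regression model whose interaction module takes explicit outer and
    inner products of projected drug and cell vectors, trained with Adam and
    early stopping. Includes cold-start (drug-blind and cell-blind) evaluation
    splits, a leave-one-view-out ablation harness, and a synthetic benchmark
    generator with a planted bilinear signal.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
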