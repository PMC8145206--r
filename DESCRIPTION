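Package: mirbw
Title: Bodyweight Prediction from Milk Mid-Infrared Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A chemometric pipeline for predicting dairy-cow bodyweight from
    milk mid-infrared (MIR) spectra together with days in milk, parity and
    milk yield. Provides a synthetic multi-herd data generator with known
    ground truth, spectral preprocessing (first-derivative transform, region
    subsetting, centering/scaling), three-stage record cleaning (parity-wise
    bodyweight ranges, global-H spectral distance, iterative PLS-residual
    screening), a NIPALS partial least squares engine with VIP and BETA
    feature-relevance scores, filter (GAM) and wrapper (recursive feature
    elimination) variable selection with tolerance-based model retention, and
    herd-independent repeated validation with external-herd evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    mgcv,
    jsonlite,
    data.table,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    optparse,
    withr
Config/testthat/edition: 3
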