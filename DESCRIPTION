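Package: mediaforge
Title: One-Step Cell Culture Media Optimization with Screening Designs and Machine Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for one-time optimization of cell culture media across
    heterogeneous donors. Constructs three-level definitive screening designs
    from conference matrices, simulates multi-donor second-order response
    surfaces with replicate noise, fits and cross-validates competing per-donor
    models (stepwise-AIC ordinary least squares, elastic net, random forest),
    screens large random in-silico formulation sets under component
    constraints, pools top-ranked candidates across donors and responses, and
    derives consensus formulations by k-means clustering with component-wise
    medians, including clustering-tendency (Hopkins) and silhouette
    diagnostics, back-evaluation in every donor model, and comparison against
    a pooled single-response regression baseline and a naive component-wise
    median ensemble.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    cluster,
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    purrr,
    ranger,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
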