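Package: eegencode
Title: Time-Resolved Linearized Encoding of Visual Features in EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale, fully testable pipeline for time-resolved
    linearized encoding analyses of visual feature processing in epoched
    EEG. Provides a synthetic-experiment generator with planted temporal
    and hierarchical structure (factorial stimulus designs, ground-truth
    feature annotations, forward-model EEG with spatially correlated
    noise, and layered network-style activations), multivariate noise
    normalization via Ledoit-Wolf shrinkage whitening, pairwise
    pseudotrial decoding with a linear support vector machine, ridge
    encoding models with validation-based regularization selection,
    split-half noise ceilings, and resampling inference (sign-permutation
    and condition-swap tests, Benjamini-Hochberg FDR, bootstrap peak
    latency confidence intervals, and an exhaustive permutation test for
    brain-network hierarchy alignment).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tools,
    tidyr,
    utils,
    yaml
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
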