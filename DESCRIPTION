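Package: neurodep
Title: Interpretable EEG Feature Pipelines for Depression Phenotyping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A seeded, desk-scale pipeline for interpretable EEG-based
    depression detection. Generates synthetic six-region EEG cohorts with
    injected spectral depression signatures, extracts a registry of 31
    multi-domain features (Hjorth parameters, Welch band powers, STFT
    spectral entropy, db4 wavelet statistics) with direction-aware regional
    aggregation, reduces dimensionality with PCA and t-SNE, classifies with
    a lightweight one-dimensional convolutional network, and explains
    predictions with Kernel SHAP attributions back-projected through PCA
    loadings onto the original EEG biomarkers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
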