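Package: fermaug
Title: Synthetic Time-Series Augmentation for Fermentation Soft Sensors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Simulates very-high-gravity ethanol fermentation experiments
    (Monod kinetics with product inhibition, online probe channels, a
    temperature cascade and realistic sensor faults), trains a convolutional
    variational autoencoder on the multivariate time series to generate
    synthetic experiments, trains feedforward soft-sensor regression models
    for ethanol concentration under original and augmented training regimes,
    and statistically compares the resulting predictive-metric distributions
    across repeated leave-one-experiment-out splits (Welch and Levene tests,
    percent-change summaries). Includes K-nearest-neighbour imputation for
    failed probe channels and fidelity diagnostics (histogram overlap,
    t-SNE embedding, prediction overlays).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    deSolve,
    car,
    stats,
    graphics,
    utils,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml,
    optparse
LinkingTo: Rcpp
Config/testthat/edition: 3
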