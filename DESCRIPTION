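Package: bovitherm
Title: Core Body Temperature Prediction for Dairy Cows from Environmental,
    Animal and Infrared Thermography Features
Version: 0.1.0
Authors@R: person("bovitherm", "maintainers", email = "bovitherm@example.org",
    role = c("aut", "cre"))
Description: A pipeline for predicting the core body temperature (rectal
    temperature) of lactating dairy cows from readily observable inputs:
    micro-environment records (air and black-globe temperature, humidity,
    wind speed, solar radiation), animal covariates (milk yield, days in
    lactation, parity, posture), and infrared surface temperatures of body
    regions. Provides biophysical feature engineering (seven thermal-comfort
    indices and a sensible/latent heat-flux model of the cow), a reproducible
    preprocessing protocol (categorical encoding, median imputation, z-score
    outlier capping), benchmark feature-set construction, cross-validated
    regression benchmarking across six model families (elastic net, neural
    network, random forest and three gradient-boosting variants backed by a
    built-in tree engine), grey-wolf-optimizer hyperparameter search, and
    TreeSHAP-based model interpretation. Includes a synthetic cohort
    generator with a known generative model so the full pipeline is testable
    without farm data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    glmnet,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
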