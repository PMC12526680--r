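Package: agripinn
Title: Physics-Informed Crop Recommendation with Stacking Ensembles
Version: 0.1.0
Authors@R:
    person("Agripinn", "Developers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Crop-recommendation modelling from soil-nutrient and climate
    measurements (N, P, K, temperature, humidity, pH, rainfall). Implements a
    physics-informed neural-network classifier whose training loss combines
    cross-entropy with a Gaussian agronomic-suitability penalty derived from
    per-crop optimal temperature and soil-pH ranges, plus random-forest,
    extra-trees and gradient-boosted-tree base learners, a stacking ensemble
    with out-of-fold probability meta-features and a multinomial logistic
    meta-learner, stratified cross-validated evaluation, a hyperparameter
    search harness (grid, random, adaptive), a class-conditional synthetic
    data generator, and command-line entry points.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    glmnet,
    jsonlite,
    yaml,
    rlang,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
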