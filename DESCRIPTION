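Package: mvfuse
Title: Multi-View Variational Autoencoder Fusion for Radiogenomic Phenotype Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts a continuous phenotype from several feature views
    (e.g. genotype-derived and imaging-derived feature tables) by learning a
    shared latent representation with a multi-view variational autoencoder
    whose per-view diagonal-Gaussian posteriors are fused in closed form by a
    product of experts, followed by a linear regression head. Includes the
    upstream genome-wide association stage used for variant feature selection
    (quality control with a Hardy-Weinberg exact test, genotype principal
    components for population stratification, covariate residualization and
    the score test), leave-one-out zero-fill feature importance, a synthetic
    data generator with the statistical structure the pipeline assumes, and a
    reproducible end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR,
    optparse
Config/testthat/edition: 3
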