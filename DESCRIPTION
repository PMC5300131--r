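Package: lvrnet
Title: Elastic Network Simulation of Emphysema Progression and Lung
    Volume Reduction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates emphysema progression in a pre-stressed hexagonal
    spring network representing lung parenchyma, and the response to lung
    volume reduction by surgical resection (LVRS) or bronchoscopic
    regional collapse (bLVR). Disease advances by probabilistic rupture
    of the highest-force elastic elements; equilibrium configurations are
    found with a force-directed simulated-annealing minimizer. The
    package computes functional measures (network stress, 2D bulk
    modulus, compliance), structural measures (airspace size
    distributions from rasterized network images, force-distribution
    heterogeneity and skewness, power-law tail exponents), and treatment
    outcome indices (failure rate, predicted survival, relative
    benefit), and orchestrates multi-network studies with responder
    classification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    jsonlite,
    yaml,
    readr,
    ggplot2,
    generics,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
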