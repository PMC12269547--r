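Package: difftrack
Title: Pointwise Inference of Heterogeneous Protein Diffusion from
    Single-Particle Tracks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and pointwise inference of heterogeneous diffusive
    behaviour in 2-D single-particle-tracking trajectories. Simulates
    fractional Brownian motion with piecewise-constant diffusion coefficient
    K, anomalous exponent alpha, and discrete behavioural state s under five
    biological models (single-state, multi-state, quenched-trap, transient
    confinement, dimerization); extracts ten hand-crafted time-series
    features; trains per-variable bidirectional LSTM sequence labellers; and
    detects and scores changepoints in the predicted series with penalized
    least-squares segmentation, Jaccard index and changepoint RMSE.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
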