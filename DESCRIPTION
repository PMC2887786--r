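Package: sirmap
Title: Small-Area Cancer Risk Mapping with Indirect Standardization,
    Spatial Screening and Bayesian Smoothing
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An end-to-end pipeline for neighbourhood-level disease
    mapping on small administrative areas: indirect standardization of
    area case counts into standardized incidence ratios (SIRs) with
    exact Poisson intervals, screening for spatial autocorrelation with
    Moran's I under a Poisson parametric bootstrap and Bonferroni
    control, Besag-York-Mollie (BYM) hierarchical smoothing by Markov
    chain Monte Carlo with exceedance probabilities and a
    spatial-fraction summary, circular Kulldorff-style Poisson scan
    corroboration, and choropleth-ready classified map layers.  Includes
    a synthetic study-region generator (irregular Voronoi tessellations,
    stratified populations, intrinsic-autoregressive risk surfaces,
    plantable risk clusters) so the whole pipeline is testable without
    confidential registry or census microdata.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
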