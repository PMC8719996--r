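Package: obstruseg
Title: Block-Based Neural Network Segmentation of Bowel-Obstruction MRI
    Phantoms with Genetic-Algorithm Initialisation and Graph-Cut Refinement
Version: 0.1.0
Authors@R: person("obstruseg", "developers", role = c("aut", "cre"),
    email = "devel@obstruseg.org")
Description: Segments 2-D grayscale abdominal images by classifying
    overlapping square blocks with a three-layer back-propagation neural
    network whose initial weights and thresholds are located by an improved
    real-valued genetic algorithm (sorting-based linear-ranking selection,
    fitness grouping, and Gaussian-mixture offspring generation), then
    refines the per-pixel class-probability map by exact max-flow/min-cut
    graph cuts.  Ships a synthetic ileus-phantom generator (dilated bowel
    loops with air-fluid levels, soft-tissue masses with irregular wall
    thickening) with paired ground-truth masks, threshold (Otsu) and
    edge-detection baseline segmenters, segmentation metrics, hidden-layer
    and block-parameter cross-validation sweeps, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    png,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
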