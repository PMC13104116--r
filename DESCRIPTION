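Package: recovnet
Title: Functional Network, Decoding and Morphology Analysis of Post-Craniotomy
    Cortical Recovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for quantifying longitudinal recovery of
    cortical microglia and neurons after craniotomy from mesoscale calcium
    imaging and fluorescence morphology data. Implements stimulus-responsive
    neuron detection against a pre-stimulus baseline criterion, population
    decoding of drifting-grating orientation (linear SVM with stratified
    cross-validation, LDA embeddings), Pearson functional-connectivity
    networks at the neuron and brain-region level with modularity, degree
    centrality, strong-connection ratio and spectral partitioning, Sholl
    and 2-D intensity morphology metrics for microglia, and day-1-baseline
    normalization, daily linear interpolation and sliding-window
    lag-correlation of longitudinal multimodal series. A synthetic-data
    module generates calcium sessions across post-operative timepoints,
    longitudinal morphology series with injected cross-modal lags, and
    analytic cell images, so every stage is testable without raw data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    e1071,
    emmeans,
    jsonlite,
    tiff
Suggests:
    igraph,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
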