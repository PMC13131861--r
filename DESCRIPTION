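Package: sundowner
Title: Brain-Behavior Covariance, Co-Activation Networks, and Circadian
    Behavior Analytics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for studying time-of-day dependent behavioral
    and neural phenotypes in mouse dementia models. Implements behavioral
    partial least squares correlation (PLSC) with permutation and
    bootstrap-ratio inference, brain-wide immediate-early-gene co-activation
    networks with proportional thresholding and graph-topology sweeps,
    hierarchical clustering of regional co-activity on a 1 - |r|
    dissimilarity with UPGMA linkage, repeated stratified cross-validated
    multinomial classification of behavioral metrics, cosinor rhythm
    estimation, sliding-window EEG spectral analysis with rule-based sleep
    staging, and arena-geometry analytics for open-field and elevated
    plus maze trajectories. A seeded synthetic-data module generates
    datasets with planted covariance, rhythm, hypnogram, spectral, and
    zone-preference structure so every pipeline stage is testable without
    animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    igraph,
    jsonlite,
    nnet,
    stats,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
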