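Package: bfndecode
Title: Brain Functional Networks and Hierarchical Linear Decoding of Hand
    Trajectories from EEG
Version: 0.1.0
Authors@R:
    person("BFN", "Maintainers", email = "maintainers@bfndecode.org",
           role = c("aut", "cre"))
Description: Constructs band-specific brain functional networks from
    multichannel EEG (Morlet wavelet envelopes, Spearman correlation,
    cost-thresholded weighted graphs), summarizes small-world graph metrics
    across hand motion modes, selects characteristic frequency bands and
    electrodes by Kruskal-Wallis tests on node degrees, and decodes 3-D hand
    position from lagged EEG with a two-level hierarchical linear model in
    which epoch-level network metrics modulate the regression intercept and
    slopes. Includes preprocessing (notch, low-pass, decimation),
    EEG/trajectory synchronization and epoching, a multiple linear regression
    baseline, cross-validated Pearson-correlation scoring with reference-range
    ROC, and a seeded synthetic-data generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr
Config/testthat/edition: 3
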