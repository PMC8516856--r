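Package: meadev
Title: Developmental Analysis of Spontaneous Network Activity on
    Microelectrode Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Characterizes and predicts the developing spontaneous activity of
    cultured neuronal networks recorded on microelectrode arrays (MEAs).
    Provides max-interval burst detection, the spike time tiling coefficient
    (STTC) with density-based clustering of synchronized electrodes,
    functional connectivity graphs with node degree, clustering coefficient
    and global efficiency, and an 18-feature electrophysiological profile per
    recording. Per-dish developmental trajectories are clustered with a
    self-organizing map followed by k-means under Davies-Bouldin model
    selection, and third-week feature levels are predicted from first-week
    features with MARS, SVM and random-forest regression evaluated by R
    squared, RMSE and regression error characteristic curves, including
    SMOTE-augmented repeated cross-validation for feature-group importance.
    A seeded synthetic cohort generator emulates dense-culture development so
    every stage of the pipeline can be validated against a known ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    igraph,
    e1071,
    randomForest
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
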