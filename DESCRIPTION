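Package: ethoclust
Title: Unsupervised Pattern Discovery in Animal Behavioral-Test Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for exploratory, unsupervised analysis of tracked animal
    trajectories from standardized behavioral-test trials (e.g., the canine
    "stranger test"). Reads per-trial tracking output (JSON time series of
    positions with detection confidence), preprocesses tracks (gap
    interpolation, smoothing, confidence-based quality control), computes a
    panel of eleven movement features (approach timing and speed, trajectory
    length, convex-hull area, intensity of use, straightness, contact time),
    enumerates PCA dimensionality-reduction scenarios clustered by k-means
    with elbow-selected k and silhouette scoring, and characterizes retained
    clusters with a formal directional "explanatory feature" statistic.
    Includes a correlated-random-walk trial simulator with known phenotype
    structure for end-to-end validation, and rank-sum comparison of clusters
    against external per-subject scores.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    cluster,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
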