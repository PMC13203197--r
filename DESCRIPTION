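Package: taiscore
Title: Time-Weighted Aggression Index Scoring from Pose Tracks and
    Behavior-Classifier Confidence Traces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies individual aggressiveness in resident-intruder
    trials from markerless pose-tracking trajectories and per-frame
    behavior-classifier confidence traces. Converts confidence traces
    into discrete behavioral bouts with a confidence threshold and a
    minimum bout duration, computes per-trial durations, first-attack
    latency and pose-derived kinematic features (relative movement
    distance, freezing duration), combines them into the Time-weighted
    Aggression Index (TAI), and derives the index weights by multiple
    linear regression. Includes quartile stratification into aggression
    groups, a method-agreement battery (Pearson/Spearman correlation,
    two-way consistency intraclass correlation, Bland-Altman limits of
    agreement), k-means clustering of index versus hemolymph serotonin
    with silhouette and bootstrap Jaccard stability, Kruskal-Wallis with
    Dunn's post hoc for pairing trials, and a synthetic-cohort generator
    emulating the statistical structure of the assay.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
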