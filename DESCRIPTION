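Package: telka
Title: Telomere Length Densitometry and Length-Kinetics Clustering
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Measures yeast telomere length from Southern teloblot scans by
    densitometry: lanes are located on the image, each lane profile is
    background-corrected by morphological opening, the two restriction-marker
    bands (2044 and 779 bp by default) anchor an exact log-linear
    migration-size calibration, and the terminal restriction fragment smear is
    summarised by its intensity-weighted median size. Relative telomere-length
    trajectories over serial re-streaks are assembled into a kinetics matrix,
    clustered hierarchically, and cluster significance is assessed with a
    permutation test on the intra-cluster distance statistic, including
    selection-adjusted sub-cluster validation. A synthetic teloblot renderer
    and trajectory simulator with known ground truth make every stage
    testable without laboratory data. Results export to CSV and to
    Cluster3-compatible CDT/GTR files viewable in Java TreeView.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    glue,
    png,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    tools,
    utils,
    withr,
    yaml,
    zoo
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
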