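Package: qccmap
Title: Digital Tumor Maps and Spatial Clustering Statistics for Rare
    Quiescent Cancer Cells
Version: 0.1.0
Authors@R:
    person("Jonas", "Wehrle", email = "jwehrle@posteo.net",
           role = c("aut", "cre"))
Description: Identifies rare quiescent cancer cells (QCCs) in per-cell
    quantitative immunofluorescence tables using relative (percentile-rank)
    thresholds on a three-marker panel (pan-AKT low, H3K9me2 low, HES1
    high), builds whole-section digital tumor maps by de-convoluting
    per-tile cell coordinates into a single Cartesian system, and
    quantifies QCC abundance (QCC-P, QCC-D) and spatial clustering via a
    window-censored k-nearest-tumor-cell cluster index (QCC-CI) with a
    label-permutation null and empirical p-values.  Includes cohort-level
    group comparisons, correlations and a post-hoc power computation, plus
    a synthetic-data generator (complete spatial randomness or Thomas
    cluster process, class-conditional log-normal intensities, batch
    scaling) so the whole pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
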