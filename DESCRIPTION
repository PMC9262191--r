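Package: mitotraj
Title: Single-Cell Analysis of Mitotic Progression in 2D+t Microscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantitative analysis of mitotic progression from time-lapse
    fluorescence microscopy of chromatin-labelled nuclei. Detects nuclei by
    multi-scale Laplacian-of-Gaussian filtering, links them backward in time
    with Ward-linkage hierarchical clustering, annotates cell-division events
    and extracts mitotic trajectories with configurable pre-/post-division
    windows. Segments the central cell of each tracked patch with a modified
    Otsu threshold and a two-seed watershed on the inverted Euclidean distance
    map, optionally merging externally produced instance-segmentation labels.
    Computes classical region features, Haralick texture features from 64-level
    co-occurrence matrices, and second-channel (spindle) features on dilated,
    eroded and toroidal masks. Synchronizes trajectories on the
    interphase-to-prophase and anaphase-onset transitions via temporally
    constrained clustering, a sister-distance heuristic and HMM/Viterbi
    decoding, and supports manual annotation files. Derives smoothed,
    event-normalized and recovery features, grouped statistics (t-test, ANOVA,
    Wilcoxon, Kruskal-Wallis, two-way treatment-by-time ANOVA), fold-change
    feature ranking with an HTML report, and aligned time-series plots. A
    synthetic mitotic-movie generator with complete ground truth makes the
    whole pipeline testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    tiff,
    signal,
    stats,
    utils,
    grDevices,
    graphics,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
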