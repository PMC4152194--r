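Package: signedfc
Title: Signed Weighted Functional-Connectivity Network Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds signed, fully-connected functional-connectivity networks
    from region-of-interest (ROI) time series via Fisher-z partial
    correlation, partitions them into modules by maximizing a generalized
    modularity index for networks with positive and negative weights
    (Louvain-type optimization), detects network hubs from generalized
    strength and diversity coefficients, and quantifies reproducibility of
    the modular organization across subjects and subject groups with
    normalized mutual information and variation of information against
    weight-permutation null networks. Includes a planted-partition
    BOLD-like cohort simulator so the entire pipeline is testable without
    imaging data, plus ROI-mean extraction from NIfTI volumes.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    withr,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse
Config/testthat/edition: 3
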