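Package: kinectome
Title: Whole-Body Movement Networks from Motion-Capture Gait Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds "kinectomes" -- marker-by-marker Pearson correlation
    networks of acceleration and jerk time series recorded during a gait
    cycle -- and analyses them with graph-theoretical tools: Louvain
    community detection with consensus clustering and allegiance matrices,
    test-retest fingerprinting (identifiability matrix, I-self, I-others,
    I-diff, identification rate), intraclass-correlation-based edge
    selection with random null curves, and weighted-degree features for
    predicting clinical motor impairment via cross-validated multilinear
    regression. Includes readers for C3D and delimited motion-capture
    trials and a synthetic gait-cohort generator with controllable subject
    signatures, left-right asymmetry and trunk-limb coupling for end-to-end
    testing of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    signal,
    car,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
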