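Package: eznet
Title: Epileptogenic-Zone Localization from EEG and SEEG Network Topology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for localizing the epileptogenic zone (EZ) in
    drug-resistant epilepsy from multichannel electrophysiology. Scalp EEG and
    stereo-EEG (SEEG) epochs are band-pass decomposed into seven frequency
    bands, converted to Pearson-correlation functional networks by absolute
    thresholding, and summarized by four nodal graph metrics (degree,
    clustering coefficient, local efficiency, betweenness centrality).
    EZ-vs-NEZ contrasts use paired Wilcoxon signed-rank tests with
    Benjamini-Hochberg correction, plus an EZ/NEZ sub-network density
    analysis. Scalp recordings pass through an sLORETA inverse solution on an
    analytic multi-shell spherical head model before network construction.
    Nodal features feed patient-grouped nested cross-validation with five
    classifiers and permutation testing. A synthetic cohort generator with
    known EZ structure makes every stage testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    MASS,
    stats,
    utils,
    jsonlite,
    e1071,
    ranger,
    xgboost,
    glmnet,
    class
Suggests:
    testthat (>= 3.0.0),
    igraph,
    pROC,
    yaml,
    optparse
Config/testthat/edition: 3
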