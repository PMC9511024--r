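Package: connvar
Title: Brain Network Graph Metrics and BOLD Variability After Cranial Radiotherapy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Resting-state fMRI analysis pipeline relating brain-network graph
    metrics (modularity, global efficiency) and ICA-derived network BOLD signal
    variability to radiotherapy exposure, memory performance, cerebral-microbleed
    burden, and clinical risk factors in young brain-tumor survivors. Includes a
    synthetic parcellated-BOLD cohort generator with planted modular covariance,
    group-ordered connectivity and variability effects and realistic confound
    structure; denoising (outlier scrubbing, confound regression, bandpass
    filtering, spatial smoothing) with degrees-of-freedom accounting;
    connectivity matrix construction and r-thresholded graph analysis; group
    spatial ICA with template matching, dual-regression backprojection and
    reproducibility sweeps; and group-level statistics (Wilcoxon rank-sum
    orderings, age-normalized metric-memory correlations, microbleed-burden
    binning with quadratic trend, risk-factor regressions).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    igraph,
    e1071,
    tibble,
    dplyr,
    tidyr,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
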