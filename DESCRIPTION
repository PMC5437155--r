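Package: gigiva
Title: Multi-Subject fMRI Decomposition with GIG-ICA and IVA-GL
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating subject-specific brain functional networks
    from multi-subject functional MRI data with two decomposition strategies:
    group information guided independent component analysis (GIG-ICA), which
    refines group-level independent components into subject-specific maps by
    jointly maximizing negentropy and correspondence with the group reference,
    and independent vector analysis (IVA-GL), which jointly decomposes all
    subjects while maximizing dependence within each source component vector.
    Includes a simulator of fMRI-like multi-subject data (Gaussian-blob
    sources with per-subject spatial perturbations, haemodynamically smoothed
    time courses, Rician noise at a specified contrast-to-noise ratio),
    greedy component/template matching and accuracy statistics, test-retest
    reliability machinery (one-sample t maps with FDR masks, one-way ANOVA
    intraclass correlation), and functional network connectivity analysis
    (signed-network modularity, adjusted mutual information, weighted graph
    metrics).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    RNifti,
    jsonlite,
    withr
Config/testthat/edition: 3
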