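Package: couplingbench
Title: Benchmarking Interregional Coupling Estimators for Resting-State fMRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Evaluation pipeline for interregional functional-coupling and
    effective-connectivity estimators computed from parcellated resting-state
    fMRI time series. Implements eleven estimators (Pearson, Spearman, full and
    L1-regularized partial correlation, time- and frequency-domain mutual
    information, spectral and wavelet coherence, information-decomposition
    redundancy and synergy, and regression dynamic causal modeling with full,
    incoming and outgoing views), motion quality-control statistics (QC-FC
    correlations and their distance dependence, framewise displacement with
    respiratory-band filtering, three-rule participant exclusion), parametric
    empirical-Bayes site harmonization, and family-aware nested cross-validated
    kernel ridge regression for behavioral prediction with permutation
    significance and false-discovery-rate control. A synthetic cohort generator
    with known network, motion-artifact, site and brain-behavior structure
    makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    MASS,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    sva
Config/testthat/edition: 3
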