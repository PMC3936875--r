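Package: smokeMethNet
Title: Smoking-Associated DNA Methylation Analysis with Cell-Mixture
    Correction and Weighted Protein-Network Module Discovery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end pipeline for epigenome-wide association analysis
    of smoking on Illumina 450K beta values. Stages: reference-panel derived
    cell-mixture surrogate covariates (differential cell-type sites, top-100
    PCA scores), per-probe linear-model EWAS with Benjamini-Hochberg
    correction, promoter-level differential methylation by flattened
    promoter-vector t-tests, conversion of a protein-protein interaction
    edge list into a p-value-weighted network, greedy discovery of
    high-scoring sub-networks by parametric local modularity with a
    permutation null, and hypergeometric GO over-representation analysis.
    Includes synthetic-data generators that emulate the cohort, purified-cell
    reference panel, interaction network and annotation inputs, so every
    stage is testable without external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    igraph
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
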