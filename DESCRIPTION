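Package: topomol
Title: Element-Specific Persistent Homology Featurization of Molecules and
    Protein-Ligand Complexes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Topological featurization machinery for small molecules and
    protein-ligand complexes: element-specific, multi-level, interactive,
    correlation-based and electrostatic filtration matrices; Vietoris-Rips
    and alpha-complex persistent homology (dimensions 0-2) with independent
    brute-force oracles; binned and statistical barcode vectorization
    including multi-channel 2-D topological images; bottleneck and
    Wasserstein barcode-space metrics; k-nearest-neighbour and tree-ensemble
    learners with consensus voting; and enrichment-factor/AUC evaluation for
    virtual screening.  Deterministic synthetic-structure generators emulate
    every input so the full pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    bio3d,
    jsonlite,
    stats,
    utils,
    xgboost,
    ranger
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
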