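Package: foldrank
Title: Consensus Ranking, Scoring and Evaluation of Predicted Protein Structure Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A toolkit for the non-neural computations used in integrative
    protein tertiary structure prediction pipelines: multiple sequence
    alignment (MSA) engineering (per-column depth profiling, template-based
    domain segmentation with disorder refinement, domain-MSA pairing and gap
    padding, profile-based MSA augmentation), CA-based structure comparison
    (Kabsch superposition, TM-score, GDT-TS), consensus model quality
    assessment (pairwise similarity score, score aggregation, K-means model
    clustering, diversity filtering) including the five CASP16 MULTICOM
    model-selection strategies, overlap-based fragment assembly of region
    models, and the CASP16 Z-score evaluation protocol. Ships synthetic
    generators for decoy pools, alignments and template-hit tables so the
    entire pipeline is exercisable without external data, plus a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    bio3d,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
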