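Package: codonangles
Title: Null-Model Audit of Codon-Specific Backbone Dihedral-Angle Tests
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to audit claimed associations between synonymous codon
    usage and protein backbone dihedral (phi/psi) angles. Simulates coding
    sequences under null codon-usage models (uniform, mutation-only, and
    selection-mutation-drift equilibrium scaled by gene expression), fits
    the selection-mutation-drift model by MCMC for parameter recovery,
    re-runs a codon-specific Ramachandran comparison (periodic kernel
    density estimation on the torus, a total-variation distance statistic,
    permutation significance, and Benjamini-Hochberg correction) on the
    simulated sequences, and quantifies concordance between analysis runs
    (rank correlations of test statistics, significant-pair overlap, and
    positional codon agreement). Includes a synthetic-study generator so
    the full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
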