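Package: msdnn
Title: Surrogate-Assisted Multi-State Protein Sequence Design
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Iterative sequence optimization for multi-state protein design
    with neural-network surrogates. Per-state feed-forward networks are trained
    on expensively scored candidate sequences, used to screen millions of
    random mutants, and the best-predicted candidates are fed back for exact
    scoring. Includes single-mutation and multi-mutation genetic-algorithm
    baselines, a seeded synthetic epistatic fitness landscape with a
    brute-force optimum oracle, a file-based adapter for external scorers,
    and convergence/composition analytics (normalized area above the score
    curve, iterations-to-reference, residue-frequency distances with shuffled
    null models, mutation-count histograms, generation-wise correlation).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    yaml,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
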