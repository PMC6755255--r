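Package: codacount
Title: Compositional Data Analysis of Sequencing Count Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A unified compositional data analysis (CoDA) workflow for
    count-based omics data (bulk and single-cell RNA-seq, metagenomics,
    spectrometric peak data). Provides zero handling by feature removal and
    multiplicative or Bayesian-multiplicative replacement, the family of
    log-ratio transformations (clr, alr, malr, iqlr, rclr, ilr balances)
    and the Aitchison distance, Dirichlet Monte-Carlo modelling of
    low-count uncertainty, reference-relative differential abundance with
    expected effect sizes and Benjamini-Hochberg p-values, proportionality
    analysis (rho, phi, phi-s) with permutation false discovery rates and
    network export, and differential proportionality (theta) with exact
    F-tests and design-matrix extensions. A synthetic count simulator with
    planted ground truth makes every stage testable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Matrix
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
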