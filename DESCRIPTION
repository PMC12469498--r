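Package: gpbso
Title: Gene-Pool Brain Storm Optimization for SNP Epistasis Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects high-order SNP epistatic interactions in case-control
    genotype data with a gene-pool-based Brain Storm Optimization search.
    Candidate SNP combinations are scored with the K2 Bayesian-network
    criterion over bit-encoded contingency tables, greedily pruned to a
    locally minimal interacting set, and filtered for significance with the
    likelihood-ratio G-test. Includes a Hardy-Weinberg penetrance-model
    simulator for case-control data with planted interactions, an
    F-measure/power evaluation harness, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
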