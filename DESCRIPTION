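Package: mitotwin
Title: Discovery and Characterization of Co-Existing Divergent Mitochondrial Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for detecting and characterizing two deeply divergent
    mitochondrial genomes co-existing within one individual, as in the
    Tuatara (Sphenodon punctatus). Implements divergence-threshold
    partitioning of sequencing reads and contigs between two candidate
    mt-molecules, coverage and mixture-fraction estimation, mitogenome
    validation (strand composition, vertebrate mitochondrial translation,
    tRNA cloverleaf folding, replication-origin stem-loops), pairwise
    p-distance and molecular-clock dating, exact branch-and-bound maximum
    parsimony with bootstrap, decay indices, constrained searches and
    Templeton Wilcoxon signed-ranks tests, and signed circular gene-order
    comparison. A synthetic-data generator emulates the two-molecule read
    mixture so the whole analysis can be exercised end-to-end against
    known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    ape,
    Biostrings,
    IRanges,
    Rsamtools,
    jsonlite,
    stats,
    utils,
    tools,
    methods
LinkingTo: Rcpp
Suggests:
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
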