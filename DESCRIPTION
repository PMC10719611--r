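Package: phylotox
Title: Phylogenetic Analysis of Toxin Tolerance Evolution
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for inferring the phylogenetic history of a binary
    physiological trait (alpha-amanitin tolerance in mushroom-feeding
    Drosophila) from per-locus sequence alignments and larval survival
    assays. Implements TIGER-style per-site evolutionary rate scoring with
    ten-bin assignment and cumulative-bin alignments, Robinson-Foulds tree
    distances with classical multidimensional scaling and centroid-distance
    locus ranking for phylogenomic sensitivity analysis, desk-scale tree
    estimation (Jukes-Cantor distances, neighbor joining with bootstrap
    support, quartet-score species trees), exact marginal and Bayesian MCMC
    ancestral state reconstruction under a symmetric two-state Markov model,
    Sankoff parsimony loss counting, and Firth bias-reduced binomial
    logistic regression for survival assays. A seeded synthetic-data module
    generates trees, locus alignments, binary trait histories and vial-level
    survival counts so that every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    seqinr,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
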