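Package: schemeval
Title: Benchmarking 16S rRNA Amplicon Classification Schemes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to evaluate taxonomic classification schemes for 16S rRNA
    amplicon sequencing at the species level. A classification scheme is the
    triple of a reference database, an identifier (a variable region of the
    16S gene amplified by a primer pair), and a classifier algorithm. The
    package generates computational amplicons by IUPAC-aware in silico PCR
    anchored on a reference row of a multiple sequence alignment, profiles
    region variability with gap-weighted Shannon entropy, classifies queries
    with a k-mer naive Bayes classifier and an alignment-based Bayesian
    lowest-common-ancestor classifier (each with bootstrap confidence
    scores), and scores schemes with a record-pair confusion framework
    (precision, recall, F-measure, Cohen's kappa) under confidence-score
    thresholds. A synthetic 16S-world generator with conserved/variable block
    architecture, planted primer sites, species dropout, and substitution
    noise makes the full pipeline testable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    e1071,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
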