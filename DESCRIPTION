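Package: profam
Title: Profile-Based Two-Tier Classification of DNA-Binding Protein Families
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A self-contained toolkit for protein-centric, two-tier (group /
    family) classification of DNA-binding proteins from sequence alone. Builds
    position-specific score matrices (PSSMs) from family alignments with
    iterative refinement and empirical E-value calibration, selects family
    representatives by leave-one-out (jack-knife) coverage with greedy
    combination aiming at 100% family coverage, triages new sequences
    against a database of representative profiles, resolves ternary complexes
    chain-wise, clusters unassigned sequences into candidate new families by
    single-linkage over pairwise profile associations, and generates seeded
    synthetic protein families, decoys and full planted-truth benchmarks for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    igraph,
    jsonlite,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
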