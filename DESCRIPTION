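Package: refselect
Title: Reference Sequence Selection for Planted (l,d) Motif Search
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Preprocessing for pattern-driven planted (l,d) motif search.
    Selects k reference sequences from a motif-search dataset so that
    pattern-driven solvers generate few candidate motifs. Implements exact
    counting of candidate motifs shared by pairs of l-mers, an O(n^2)
    dynamic program for all-pairs l-mer Hamming distances, Markov
    clustering of the induced sequence-similarity graph with greedy
    cluster refinement, an exhaustive-search baseline, a planted-motif
    benchmark generator, and evaluation metrics, together with a command
    line interface that reorders the input so the selected references
    come first.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    Biostrings,
    parallel,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
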