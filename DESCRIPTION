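Package: spaq
Title: Alignment-Free Phylogeny from Spaced-Word Quartet Blocks
Version: 0.1.0
Authors@R:
    person("spaq", "developers", email = "spaq@example.org", role = c("aut", "cre"))
Description: Reconstructs phylogenetic tree topologies from unaligned genome
    sequences. Gap-free four-taxon micro-alignments ("quartet P-blocks") are
    sampled at occurrences of a common spaced word defined by a binary
    match/don't-care pattern, filtered by a substitution-score homology test.
    For each block the maximum-likelihood quartet topology is inferred under
    GTR+Gamma via Felsenstein pruning, and the conclusive quartet topologies
    are amalgamated into an unrooted supertree with a MaxCut-style recursive
    partition heuristic. Includes a sequence-evolution simulator and
    Robinson-Foulds tree comparison utilities so that accuracy is verifiable
    end-to-end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    Biostrings,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
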