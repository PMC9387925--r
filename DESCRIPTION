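Package: gapquartet
Title: Phylogenetic Signal from Indels Between Spaced-Word Quartet Blocks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Alignment-free phylogeny reconstruction from putative insertions
    and deletions. For four or more nucleotide sequences, the package finds
    quartet blocks (occurrences of one spaced word in four different
    sequences), pairs each reference block with a second downstream block,
    and compares the four inter-block distances. Equal and unequal distances
    reveal indel events and support one of the three quartet topologies;
    full trees are then assembled either by quartet amalgamation (a weighted
    max-cut heuristic) or by maximum parsimony on a character matrix encoding
    the distances. Includes a seeded sequence-evolution simulator with
    substitutions and indels, evaluation against reference trees (quartet
    accuracy, coverage, Robinson-Foulds distances), and writers for PHYLIP,
    NEXUS and quartet-list formats.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    phangorn,
    Biostrings,
    data.table,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
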