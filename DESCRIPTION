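Package: wtfkit
Title: Evolution and Population Dynamics of Poison-Antidote Meiotic Driver
    Gene Families
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for studying the diversification of multi-copy
    poison-antidote spore-killer gene families such as the fission-yeast wtf
    family. Provides family-member discovery in genome assemblies by seeded
    local alignment, exon similarity networks and identity-threshold
    clustering, flank-based locus assignment with presence/absence matrices,
    pseudogene and poison-start-codon calling, recombination-signal testing
    (pairwise homoplasy index, triplet breakpoint scanning, four-gamete
    minimum-recombination counts), distance-based phylogenetic grouping and
    tree-imbalance summaries, exon-swap chimera construction with
    poison/antidote isoform modelling, a forward-time gene-family simulator
    with full ground-truth event logging, and Wright-Fisher models of
    poison-antidote meiotic drive.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    ape,
    igraph,
    phangorn,
    yaml,
    stats,
    utils,
    tools,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
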