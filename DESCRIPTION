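Package: neustonet
Title: Haplotype Networks, Diversity Statistics and UVR Motif Scanning
    for Mitochondrial Phylogeography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for clade-level mitochondrial phylogeography of
    surface-film (neustonic) zooplankton: reading and preprocessing
    aligned rRNA haplotype sets, collapsing haplotypes and computing
    haplotype diversity (Hd), mean pairwise differences (K, pooled Kt),
    p-distance matrices and per-sequence base-composition heterogeneity
    chi-square tests, counting UV-photolesion-salient trinucleotide
    motifs (TTA/TTT vs TTC/TTG) on both strands with overlap, building
    median-joining haplotype networks, and simulating clade-structured
    AT-rich haplotype datasets with a controllable habitat-linked
    deficit of photolesion-promoting motifs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    seqinr,
    igraph,
    jsonlite,
    stats,
    utils,
    tools,
    graphics
Suggests:
    ape,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
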