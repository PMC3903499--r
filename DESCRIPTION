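Package: tetragray
Title: Tetrahedral Gray Code Layout and Visualization of Genome k-mer
    Composition
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Constructs the tetrahedral Gray code, a bijective layout of all
    4^k DNA k-mers onto the 4^k triangular cells of a tetrahedron's
    development (net) such that every pair of edge-adjacent cells -- including
    pairs glued together when the net is folded -- differs by exactly one
    nucleotide. Provides k-mer counting, zeroth- and higher-order Markov and
    cross-genome background models, log-odds fields, CpG observed/expected
    ratios and positional log-odds matrices around CpG, a paper-craft-ready
    SVG renderer of the color-coded net, a seeded Markov-chain sequence
    simulator with controlled dinucleotide biases and planted motifs, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    BiocGenerics,
    IRanges,
    igraph,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    grDevices
Config/testthat/edition: 3
RoxygenNote: 7.3.3
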