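Package: ProtAdjacency
Title: Alignment-Free Protein Family Similarity via Adjacency Vectors and
    Group Representative Vectors
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Alignment-free similarity and dissimilarity analysis of protein
    sequence families. Each protein is summarised by its adjacency vector, a
    400-element count of every ordered pair of adjacent amino acids read left
    to right along the primary sequence. A family of sequences is summarised
    by a group representative vector, the elementwise median of the members'
    adjacency vectors. Per-sequence similarity to the representative is
    measured by the Euclidean magnitude of the difference (D) and the angle
    between the vectors (theta, radians), replacing the usual all-pairs
    similarity matrix by a linear-cost similarity vector. Cross-group
    comparison against a foreign representative, a conventional pairwise
    distance matrix mode, a class-coherence report, FASTA input with
    configurable residue validation, and a seeded synthetic family generator
    are included.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    S4Vectors,
    SummarizedExperiment,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    seqinr,
    optparse
biocViews: Alignment, SequenceMatching, Classification, Proteomics
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
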