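Package: polyAsig
Title: Discovery and Characterization of mRNA Polyadenylation Signals
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for characterizing the cis-elements that direct mRNA
    cleavage and polyadenylation. Extracts strand-corrected 400-nt windows
    around mapped poly(A) sites, removes internal-priming artifacts,
    exhaustively scans and ranks 3-8 nt motifs in defined signal regions
    (FUE, NUE, CE) under overlapping, non-overlapping (gap) and once
    counting modes, scores motif over-representation with Z-scores against
    order-m Markov backgrounds, infers signal regions from single-nucleotide
    positional profiles, compiles single-nucleotide variant groups of
    canonical signals with position frequency matrices and PSSM scoring,
    and ships a seeded synthetic-data generator that provides ground truth
    for the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr
biocViews: Sequencing, MotifDiscovery, SequenceMatching, Transcriptomics
Config/testthat/edition: 3
RoxygenNote: 7.3.3
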