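Package: castscan
Title: Characterization of CRISPR-Associated Transposase Integration Products
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Sequencing-based characterization of CRISPR-associated
    transposase (CAST) integration products. Provides a deterministic
    synthetic-read simulator with machine-readable ground truth (amplicon,
    UMI-tagged unidirectional, and long reads), transposon-genome junction
    calling with insertion-distance profiling and orientation classification,
    target-site-duplication and indel fidelity metrics, simple-insertion
    versus cointegrate classification of long reads, and UMI-deduplicated
    genome-wide integration-site discovery with on/off-target labeling,
    target-homology scanning, and replicate-overlap analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    methods,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
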