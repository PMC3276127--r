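Package: SatelliteSeeker
Title: De Novo Discovery and Characterization of Subtelomeric Satellite
    Repeats from Low-Coverage Shotgun Reads
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies satellite-repeat families de novo from low-coverage
    (sub-1x) whole-genome shotgun reads by all-vs-all similarity-graph
    clustering, reconstructs circular tandem-repeat monomer consensus
    sequences by greedy k-mer-frequency extension, estimates repeat genome
    proportions from cluster read counts, segments and classifies
    subtelomere junction clones against monomer and telomere references,
    and calibrates fiber-FISH signal lengths into physical DNA sizes and
    size categories. Includes a synthetic-data generator that emulates
    shotgun sampling of genomes carrying long tandem arrays at chromosome
    ends (telomere, then a distal satellite array, then a proximal one).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    S4Vectors,
    Matrix,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
biocViews: Sequencing, Clustering, Alignment, RepeatAnalysis
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
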