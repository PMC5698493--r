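Package: bgcdose
Title: Copy-Number and Gene-Dosage Inference for Repeated Biosynthetic
    Gene Clusters in Degrading Symbiont Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers the copy number and effective gene dosage of large
    repeated regions (such as secondary-metabolite biosynthetic gene
    clusters) in collapsed assemblies of bacterial symbiont genomes.
    Provides windowed read-depth profiling, integer copy-number
    segmentation, deletion-carrier counting, intact-genome-size
    expansion, paired-end contig connection graphs, single-copy-marker
    bin quality metrics, pseudogene calling from homolog length ratios,
    Sharp-Li codon adaptation index analysis, amplicon read
    classification, and exact-repeat quantification, together with a
    synthetic-data generator that produces genomes, paired-end
    alignments, gene models and amplicon mixtures with known ground
    truth for validating every stage of the inference chain.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    igraph,
    rtracklayer,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
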