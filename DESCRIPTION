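Package: mxefinder
Title: Prediction of Mutually Exclusive Exons from Annotated Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Enumerates, scores and classifies candidate mutually exclusive
    exons (MXEs) in annotated eukaryotic genomes. Starting from a genome FASTA
    and a coding-gene GFF3 annotation, the package reconstructs validated gene
    models, scans introns and gene flanks for exon candidates bounded by
    canonical splice sites that preserve the reading frame and resemble the
    original exon in length and peptide sequence, filters and clusters the
    candidates, classifies clusters as initial, internal or 3'-terminal,
    detects annotated MXE clusters and MXE-like constitutive exons, and
    summarises whole-exome statistics including sensitivity against the
    annotation. A deterministic synthetic-genome generator with planted exon
    clusters supports end-to-end testing without any external download.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
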