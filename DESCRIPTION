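Package: ncsplice
Title: Genome-Wide Classification and Validation of Non-Canonical Splice Sites
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for surveying splice-site combinations across annotated
    genomes. Extracts CDS-flanked introns from a genome assembly (FASTA) and
    its annotation (GFF3), classifies intron border dinucleotides into
    canonical (GT-AG), major non-canonical (GC-AG, AT-AC) and minor
    non-canonical combinations, correlates combination divergence with
    frequency, validates annotated splice sites from per-base RNA-Seq
    coverage via a relative coverage-drop rule, quantifies splice-site
    usage, detects shift-equivalent alternative intron placements, and
    compares the substitution spectrum implied by minor combinations against
    genome-wide substitution rates from variant calls. Includes a seeded
    synthetic-data generator (genome, annotation, coverage tracks, VCF) with
    a ground-truth manifest for end-to-end testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    vcfR,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
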