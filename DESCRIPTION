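Package: barhem
Title: Barcoded Reciprocal Hemizygosity Screening from Pooled Competitions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for barcoded reciprocal-hemizygosity screens in
    interspecies hybrid yeast. Processes transposon-junction (Tn-seq)
    reads into a quality-controlled catalog of barcoded insertions
    (junction detection, barcode error collapsing, multi-locus and
    ambiguous-mapping filters, genic annotation), counts barcodes in
    pooled competition samples from amplicon (Bar-seq) reads restricted
    to the catalog, and performs the reciprocal hemizygosity test:
    normalization, per-clone temperature effects, genotype and gene
    quality gates, Mann-Whitney testing with Benjamini-Hochberg
    correction, allelic effect sizes and hit calling. Downstream
    resampling analyses cover gene-set overrepresentation and
    effect-size enrichment with essentiality-matched nulls, protein
    interaction enrichment, and McDonald-Kreitman tests. A synthetic-data
    generator emulates the hemizygote pool and competition experiment
    with known ground-truth allelic effects so that every stage is
    verifiable end to end.
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
    rtracklayer,
    jsonlite,
    yaml,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
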