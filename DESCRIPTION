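Package: bsaTE
Title: Bulked-Segregant Locus Mapping, LTR Retrotransposon
    Presence/Absence Classification, and Marker Segregation Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for mapping a causal locus from pooled sequencing of
    phenotypic bulks with the per-SNP Euclidean-distance statistic
    (ED^5 sliding-window scan, empirical 95% threshold, candidate
    interval calling), for classifying intact LTR retrotransposon
    insertions between genome assemblies by anchoring 500 bp flanks and
    comparing the spanned middle sequence (high shared, low shared,
    insertion, elimination, unknown), and for dating insertions from
    the divergence of the element's two LTRs under a Jukes-Cantor
    clock. Mendelian segregation chi-square tests, marker-phenotype
    co-segregation, haplotype-combination flesh-colour rules, fruit
    development period classes and carrier-ratio summaries cover the
    accompanying statistical genetics. A seed-deterministic simulator
    generates F1 crosses with Haldane recombination, pooled allele
    depths, and genomes with planted LTR elements, providing ground
    truth for parameter-recovery validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    graphics,
    jsonlite,
    S4Vectors,
    BiocGenerics,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    SummarizedExperiment,
    VariantAnnotation
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
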