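Package: fdlpminer
Title: Mining and Annotation of Fungal Defensin-Like Peptide Genes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Discovery and annotation pipeline for fungal defensin-like
    peptides (fDLPs) in nucleotide assemblies. Finds candidate loci by
    six-frame translation, cysteine-framework motif matching and
    Smith-Waterman similarity to a seed set of mature defensins; completes
    spliced gene models across GT-AG introns with intron-phase annotation;
    segments precursors into signal peptide, propeptide(s) and one or two
    mature CSab-defensin domains with C-terminal amidation detection;
    computes molecular weight and Henderson-Hasselbalch net charge;
    classifies mature peptides into families with a neighbor-joining tree
    and bootstrap support; and analyses tandem gene duplication including
    synonymous substitution counts between paralogs. Includes a synthetic
    genome generator that plants defensin genes with known architectures
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    BiocGenerics,
    S4Vectors,
    rtracklayer,
    ape,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
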