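Package: editome
Title: A-to-I RNA Editome Discovery, Quantification and Differential Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for profiling adenosine-to-inosine (A-to-I) RNA editing from
    aligned RNA-seq data. Calls candidate single-nucleotide variants from read
    pileups, applies a cascade of artifact and germline filters (homopolymers,
    simple repeats, the mitochondrial genome, splice-junction and indel
    proximity, read-end bias, known SNPs, and cross-sample allele-frequency
    genotype patterns) to retain high-confidence A-to-I sites, quantifies
    per-site editing levels and per-gene TPM expression, annotates sites by
    genomic region and coding consequence, and tests for differential editing
    with a binomial GLM likelihood-ratio test. Includes a synthetic editome
    generator with ground truth (edited transcripts, germline variants,
    planted artifacts) so the whole pipeline can be exercised end to end
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.2)
Imports:
    data.table,
    stats,
    utils,
    tools,
    methods,
    Biostrings,
    IRanges,
    GenomicRanges,
    GenomicAlignments,
    S4Vectors,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    seqinr,
    optparse
Config/testthat/edition: 3
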