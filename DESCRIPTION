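Package: rloopscan
Title: Strand-Specific R-Loop Peak Analysis and Sequence-Grammar Association
Version: 0.9.0
Authors@R: person("rloopscan", "maintainers", email = "rloopscan@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing strand-specific R-loop mapping data and the
    sequence grammar of R-loop-prone regions. Provides a synthetic-data
    generator (genome, gene models, planted G-cluster/T-run motifs, stranded
    coverage, negative-binomial count matrices), a stranded Poisson peak
    caller with condition comparison and genomic-context annotation,
    non-template-strand sequence features (GC skew, G%, T%, T-run inventory,
    k-mer enrichment), an SVM classifier of R-loop-prone regions with a
    genome scanner, differential-expression testing with gene-length and
    motif-burden association, and a two-species contrast of gene-length
    effects.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    jsonlite,
    withr,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
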