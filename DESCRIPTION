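Package: methylandscape
Title: Methylome Landscape Comparison from Per-Cytosine Bisulfite Calls
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to compare whole-genome bisulfite sequencing methylomes
    between two genotypes from per-cytosine call tables: weighted methylation
    levels in fixed genomic bins and annotation sets, threshold-based
    differential-bin calling with overlap statistics, bisulfite conversion-rate
    QC from an unmethylated spike-in contig, non-CpG (CH) context analysis with
    next-nucleotide preference, and chromatin-state segmentation of binarized
    histone-mark tracks with a multivariate Bernoulli-emission hidden Markov
    model. Includes a synthetic-data generator that emulates a bimodal oocyte
    CG methylome coupled to H3K36me2/3 domains, mutant-specific CG gain
    confined to chromatin lacking H3K36me2/3, and CA-dominant CH methylation,
    so the full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
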