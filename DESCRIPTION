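Package: epistate3c
Title: Cell States and 3D Genome Reorganization from Single-Cell Methyl-3C Data
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Statistics and procedures for joint single-cell DNA methylation
    and chromosome-conformation (snm3C-seq) cohort studies of brain disease:
    binomial hypomethylation scoring of genomic bins, global-methylation
    cell-state partitioning with instrument normalization, subtype-similarity
    clustering of pairwise log2 fold-change tensors, Gaussian-kernel
    contact-distance scoring and short/long classification, insulation-based
    boundary calling with covariate-adjusted 1-Mb boundary density,
    pseudo-bulk A/B compartment and saddle analysis with ICE balancing,
    centromere-aligned average observed/expected maps, detection of putative
    telomere-proximal deletions from balanced row sums, and per-pixel one-way
    F statistics for differential chromatin loops. Includes a synthetic
    cohort generator with planted ground truth so the full pipeline is
    testable end-to-end, and a configurable pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    data.table,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    jsonlite,
    yaml,
    pracma
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
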