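Package: DomestiScan
Title: Simulation-Calibrated Selection Scans for Canine Domestication Genomics
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Detects candidate domestication regions by contrasting village
    dog and gray wolf cohorts. Implements per-site Hudson F_ST with windowed
    ratio-of-averages, pooled heterozygosity (Hp) and the ancient-dog delta-Hp
    haplotype filter, a cross-population composite likelihood ratio (XP-CLR)
    scan, read-depth copy-number estimation with GC correction and the V_ST
    differentiation statistic, and permutation-calibrated parent-child gene
    ontology enrichment. Significance thresholds are calibrated against a
    neutral coalescent null simulated under a configurable demographic model.
    A synthetic-cohort generator with planted selective sweeps and copy-number
    differences supports end-to-end validation without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    Biostrings,
    VariantAnnotation,
    rtracklayer,
    BiocGenerics,
    pracma,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: PopulationGenetics, SNP, CopyNumberVariation, Coverage,
    GeneSetEnrichment, Software
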