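Package: drivermod
Title: Multi-Omics Driver Discovery by Module Networks, Consensus Subtyping
    and Enhancer Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An integrative multi-omics pipeline for cancer driver-gene
    discovery and molecular subtyping. Candidate regulators are selected per
    platform (mutation frequency, copy-number state, differential methylation
    with a transcriptional-predictivity filter, miRNA-target anticorrelation,
    differential expression). Co-expression modules are inferred from
    differentially expressed genes by a two-way Gibbs sampler with a
    Normal-Gamma marginal likelihood, regulators are scored against modules
    through regulation trees, and high-scoring regulators are called drivers.
    Downstream stages implement cluster-of-clusters (COCA) consensus
    subtyping with survival association, enhancer gain/loss calling from
    H3K4me1/H3K27ac signal tracks with regulatory-domain gene association,
    single-sample gene-set enrichment (ssGSEA), mutual-exclusivity tests and
    over-representation analysis. A synthetic-cohort generator with planted
    regulators, subtypes, survival differences and enhancer events provides a
    ground-truth surface for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    methods,
    survival,
    mclust,
    igraph,
    limma,
    fgsea,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
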