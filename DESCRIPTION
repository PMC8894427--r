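Package: poolSeqER
Title: Pooled-Sequencing Evolve-and-Resequence and Reciprocal-Transplant Analysis
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis toolkit for evolve-and-resequence experiments with
    reciprocal transplants, built around pooled RNA-seq allele counts and
    gene-level expression counts from replicated selection lines. Implements
    the variant filter cascade and replicate-stratified Cochran-Mantel-Haenszel
    divergence tests with multi-generation intersection into an adaptive-locus
    set; negative-binomial differential expression with plasticity-only versus
    genetic-change partitioning of adaptively diverged genes; discriminant
    analysis of principal components with projection of transplanted samples
    and Bayesian (Gibbs) inference on discriminant-space shifts; pooled
    nucleotide diversity in non-overlapping windows with targeted-erosion
    tests; rank-based (Mann-Whitney) functional enrichment; and day-structured
    Leslie-matrix estimation of the net reproductive rate. A synthetic-data
    generator reproduces the statistical structure of the full design
    (Wright-Fisher trajectories with selected loci, binomial pool and read
    sampling, negative-binomial expression with plasticity-loss effects, and
    binomial-chain life-history assays) so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    MASS,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr,
    survival,
    jsonlite,
    optparse
Config/testthat/edition: 3
biocViews: Genetics, Transcriptomics, PopulationGenetics, ExperimentalDesign
RoxygenNote: 7.3.3
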