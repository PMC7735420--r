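Package: spermclock
Title: Sperm Methylome Aging Analysis: EWAS, DMRs, Epigenetic Clock and
    Co-Methylation Modules
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for targeted bisulfite sequencing of human
    sperm across the male reproductive lifespan: parsing of genome-wide
    cytosine reports into a MethylationExperiment container, coverage and
    exclusion-region site filtering, imprinted-locus purity quality control,
    per-CpG covariate-adjusted linear-model association of methylation with
    age, Storey q-value false discovery control and genomic-control
    inflation diagnostics, direction-specific differentially methylated
    region calling (>= 5 significant CpGs in a 500 bp window), nearest-TSS
    and interval-track annotation with GREAT-style gene density enrichment,
    an elastic-net methylation age predictor evaluated by leave-one-out
    cross-validation, and weighted co-methylation network modules with
    eigengene-trait correlation. A fully specified synthetic cohort
    generator emulating the study design (94 donors in young and old
    groups, bimodal sperm methylation baselines, binomial read counts at
    20-30x coverage, planted per-year age effects, DMR clusters,
    co-methylated modules and age-correlated clinical covariates) makes
    every stage testable without controlled-access data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    glmnet,
    S4Vectors,
    IRanges,
    GenomeInfoDb,
    GenomicRanges,
    SummarizedExperiment,
    rtracklayer,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: DNAMethylation, Epigenetics, Sequencing, Regression,
    Network, QualityControl
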