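Package: txSubstage
Title: Transcriptome-Defined Substaging of Dementia Cohorts and
    Adjacency Networks of Disease Progression
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Stratifies NCI/MCI/AD dementia cohorts into
    transcriptome-defined substages and infers adjacency networks of
    disease progression among them. Implements threshold-grid searches
    for differentially expressed gene sets, correlation-distance
    average-linkage clustering with a first-branch enrichment criterion,
    per-individual deviation counting and k-means/elbow classification
    into detailed substages, genome-wide epigenome similarity typing via
    interval Jaccard coefficients, exact r x c Fisher tests by
    enumeration, and a partition-based graph abstraction over a kNN
    graph with stage-aware pruning. A synthetic-cohort generator with
    planted substage structure, matching epigenome peak tracks and APOE
    genotypes makes every stage of the pipeline testable without
    restricted clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'fisher.R'
    'stats.R'
    'clustering.R'
    'epigenome.R'
    'genesets.R'
    'io.R'
    'trajectory.R'
    'substages.R'
    'simulate.R'
    'pipeline.R'
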