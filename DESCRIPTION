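Package: cnvDiversity
Title: Copy Number Variation Diversity Analysis for Multi-Breed SNP Array Cohorts
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Reference-relative copy number variation (CNV) analysis of
    SNP genotyping array signal intensities in structured populations.
    Builds a reference signal profile from a designated low-variance
    breed, calls per-marker CNV gains and losses from log2 intensity
    ratios, collapses calls into per-individual segment CNVs, merges
    segments across the cohort into CNV regions (CNVRs), quantifies
    breed- and cluster-private CNVs under a within-group frequency
    filter, summarizes genome coverage and population structure by
    principal component analysis of B-allele frequencies and segment
    signals, intersects CNVRs with gene/QTL/catalogue tracks with
    hypergeometric term overrepresentation, and validates calls against
    2^-ddCt qPCR copy states. Includes a synthetic multi-breed cohort
    generator with planted CNV regions and known truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    data.table,
    yaml,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
biocViews: CopyNumberVariation, SNP, Genetics, PopulationGenetics,
    StructuralVariation, QualityControl
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
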