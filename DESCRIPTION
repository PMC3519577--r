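Package: twindiff
Title: Paired DNA Methylation Discordance Analysis for Monozygotic Twin Designs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of promoter DNA methylation differences between
    monozygotic co-twins discordant for a disease phenotype, built around
    Illumina 27K-style beta-value matrices. Provides probe-level quality
    control (in-silico bisulfite-converted reference alignment, SNP-in-CpG and
    detection-P masking), global similarity and intra-pair variation
    statistics, candidate-gene and genome-wide paired t-tests with
    Westfall-Young maxT sign-flip permutation family-wise error control,
    exact noncentral-t power calculations, bisulfite-sequencing validation
    summaries, Fisher exact gene-set enrichment, and a calibrated synthetic
    twin-methylome generator for end-to-end testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    Biostrings,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'TwinBetaSet-methods.R'
    'differential.R'
    'global.R'
    'io.R'
    'pipeline.R'
    'power.R'
    'qc.R'
    'simulate.R'
    'twindiff-package.R'
    'validation.R'
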