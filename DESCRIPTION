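Package: iqscore
Title: Chance-Corrected Quality Assessment of Genotype Imputation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes the imputation quality score (IQS), a chance-corrected
    concordance statistic between true and imputed genotypes built on a 3x3
    cross-classification of genotype posterior probabilities, together with the
    companion statistics used to benchmark it (imputation accuracy, efficiency,
    MACH-style dosage variance ratio, IMPUTE-style information score, and
    minor-allele-frequency difference against a reference panel). Includes
    probability-weighted case/control trend tests, genomic inflation factors,
    Q-Q summaries and metric-based SNP filtering for detecting and removing
    imputation-driven false positives when cases and controls are genotyped on
    different platforms; a seeded synthetic cohort generator with controllable
    imputation-error models; readers and writers for Oxford GEN/SAMPLE, VCF
    genotype probabilities, metric tables and IQS database files; and a
    command-line tool wiring these together.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    data.table,
    jsonlite,
    vcfR,
    optparse
Suggests:
    testthat (>= 3.0.0),
    e1071
Config/testthat/edition: 3
RoxygenNote: 7.3.3
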