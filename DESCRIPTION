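Package: methsam
Title: Differential DNA Methylation Analysis for Severe Acute Malnutrition
    Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Covariate-adjusted differential DNA methylation analysis
    comparing edematous and non-edematous severe acute malnutrition,
    built around 450K-style beta-value matrices. Implements per-CpG
    linear-model testing on rank-inverse-normal transformed M values,
    direction-consistent clustering of CpGs into differentially
    methylated clusters (DMCs), genomic-inflation (lambda) adjustment
    and cross-cohort concordance, permutation-based GWAS-catalog (EFO)
    and Human Phenotype Ontology enrichment scores, a quartile-weighted
    gene-ontology overlap score, genotype QC and condition-dependent
    (nutrition-sensitive) cis-meQTL classification, methylation-expression
    Spearman correlation, and the exact bivariate-normal correlation
    power computation. Ships a synthetic-data generator emulating the
    statistical structure of such studies, with a ground-truth ledger
    for recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    data.table,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    limma,
    fgsea,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
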