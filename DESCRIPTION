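Package: mitonuclear
Title: Mitonuclear Discordance and Mitochondrial Gene Expression in Admixed Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to quantify mitonuclear DNA discordance in recently admixed
    cohorts and to test its association with mitochondrial (mtDNA) gene
    expression. Classifies mtDNA haplogroups into continental ancestry
    designations, computes a per-individual discordance statistic from K=2
    global-ancestry fractions, adjusts TPM expression for donor age and tissue
    ischemic time, and runs three association analyses (one-sided Mann-Whitney
    U with common-language effect sizes, a label-permutation test on mean
    expression differences between low- and high-discordance groups, and
    one-sided Spearman rank correlation, all Bonferroni-corrected within
    tissue). Also implements an unweighted block-bootstrap enrichment test of
    local ancestry at 5-Mb windows around nuclear-encoded mitochondrial genes,
    readers and writers for ADMIXTURE-style Q tables, GCT v1.2 expression
    matrices, RFMix MSP-style local-ancestry tables and BED gene annotations,
    and a seeded synthetic admixed-cohort generator for testing the full
    pipeline without access to protected genotype data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
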