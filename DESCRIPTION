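Package: eqtlscan
Title: Cis- and Trans-eQTL Mapping with Permutation FDR and a Filter Cascade
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end expression quantitative trait locus (eQTL) discovery
    and interpretation for microarray expression profiles and dense SNP
    genotypes. Covers genotype quality control (exact Hardy-Weinberg test,
    minor-allele-frequency and missingness filters), 75th-percentile-shift
    normalization, covariate and surrogate-variable adjustment, additive
    single-SNP association scans, cis-eQTL calling by permutation-based
    false discovery rate on per-transcript minimum P values, trans-eQTL
    calling by Bonferroni family-wise control followed by a conditional
    regression, linkage-disequilibrium pruning, cross-hybridization and
    low-expression exclusion cascade, gene-structure enrichment and
    Jonckheere-Terpstra trend statistics, multi-regulatory eQTL detection,
    and reclassification of GWAS catalog records into interpretive cases.
    A synthetic-data generator with a truth table makes every stage testable
    without access to cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml,
    Biostrings,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
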