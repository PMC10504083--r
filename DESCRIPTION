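Package: sbqtl
Title: Sex-Biased QTL Mapping and Sex-Stratified Causal Integration for
    Molecular Traits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying sex differences in the genetic regulation of
    molecular traits (protein or transcript abundance). Implements
    sex-differential expression scanning with surrogate-variable protection of
    the sex effect, a two-stage sex-biased QTL (sb-QTL) procedure (stage 1:
    joint and sex-stratified cis-QTL scans; stage 2: genotype-by-sex
    interaction testing with FDR control), X-chromosome hemizygous dosage
    coding, greedy LD clumping to index variants, Storey pi1
    discovery/replication statistics, environment-interaction confounding
    checks, and sex-stratified causal integration via cis heritability,
    penalized expression-weight training, summary-statistic PWAS and
    approximate-Bayes-factor colocalization. A synthetic-data module generates
    LD-structured genotypes, sex-affected expression and sex-stratified GWAS
    summary statistics with a fully known truth table so every stage is
    testable end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    glmnet,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
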