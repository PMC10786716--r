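Package: prsbridge
Title: Cross-Ancestry Polygenic Scores by Two-Stage Bayesian Ridge Regression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constructs polygenic risk scores (PRS) for an underpowered target
    ancestry by bridging effect-size information from a well-powered discovery
    genome-wide association study (GWAS). Within linkage-disequilibrium-defined
    loci, SNP effects are estimated by conjugate Bayesian ridge regression on
    GWAS summary statistics (stage 1); the discovery-population posterior then
    serves as the prior for the target-population update under a grid of
    bridging strengths (stage 2). Candidate scores over the prior grids are
    combined by cross-validated ridge stacking, and the two-stage, target-only
    and merged models are weighted by approximate posterior model
    probabilities. Includes PLINK bed/bim/fam and summary-statistic readers, a
    two-population genotype-phenotype simulator with configurable allele
    frequency divergence, linkage disequilibrium and cross-population effect
    correlation, and covariate-adjusted bootstrap evaluation of variance
    explained.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    boot,
    data.table,
    digest,
    dplyr,
    generics,
    ggplot2,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    glmnet,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
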