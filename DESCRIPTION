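Package: twinmeth
Title: Within-Pair Differential Methylation Analysis for Discordant
    Monozygotic Twin WGBS Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing whole-genome bisulfite sequencing data from
    monozygotic twin pairs discordant for a phenotype. Provides readers for
    Bismark-style cytosine reports and coverage files, CpG-level quality
    filters (joint coverage, strand concordance, blacklist removal, lambda
    spike-in conversion efficiency), threshold-based calling of
    differentially methylated positions within pairs with a
    coefficient-of-variation gate, rule-based construction of differentially
    methylated regions with empirical-Bayes beta-binomial shrinkage,
    gene-model annotation with hypergeometric over-representation testing,
    twin-similarity statistics (pairwise correlations, variably methylated
    region masking, Kolmogorov-Smirnov comparison of within-pair and
    unrelated differences), and a synthetic-cohort simulator with planted
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    yaml
Config/testthat/edition: 3
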