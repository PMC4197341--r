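Package: ccrvsim
Title: Case-Cohort Rare-Variant Association Simulation and Testing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and evaluation framework for aggregate rare-variant
    association tests under a case-cohort sequencing design in which a random
    subcohort is enriched with individuals sampled from the extremes of
    correlated quantitative traits. Provides a signed doubling construction of
    Student-t components for correlated trait generation, synthetic
    targeted-region rare-variant genotypes with missingness and high-risk
    annotation flags, MAF-dependent causal-effect injection, four aggregate
    association tests (unweighted and MAF-weighted burden regressions, a
    variance-component score test with mixture-of-chi-square p-values, and a
    weighted score test with permutation p-values), and replicate engines for
    empirical type I error and power with binomial confidence intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
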