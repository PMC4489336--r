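Package: winsig
Title: Genome-Wide Significance Thresholds for Sliding-Window Tests of
    Rare Variants in Whole-Genome Sequencing Studies
Version: 0.1.0
Authors@R:
    person("Analysis", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimates family-wise-error-controlling significance
    thresholds for whole-genome sequencing association scans that combine
    single-marker tests of common variants with overlapping sliding-window
    tests (burden, SKAT, SKAT-O) of rare variants.  Provides analytic null
    correlations between window test statistics, eigenvalue-based
    estimators of the effective number of independent tests, and an
    empirical pipeline that simulates null phenotypes, sections the
    chromosome, extracts empirical minimum-P thresholds, and extrapolates
    a genome-wide significance level by linear regression against the
    Bonferroni scale.  Includes a seedable synthetic-cohort generator
    (mosaic haplotype copying over a founder panel) emulating a
    chromosome-scale genotype matrix with a rare-skewed allele-frequency
    spectrum and distance-decaying linkage disequilibrium.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    jsonlite,
    VariantAnnotation,
    GenomicRanges,
    SummarizedExperiment,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
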