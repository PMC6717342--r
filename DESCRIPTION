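Package: vafrank
Title: Variant and Gene Prioritization for Small Targeted-Sequencing
    Cohorts
Version: 0.1.0
Authors@R:
    person("vafrank", "authors", email = "dev@example.org",
           role = c("aut", "cre"))
Description: Analytical workflow for targeted-sequencing variant data from
    small two-group cohorts (e.g. drug-sensitive versus drug-resistant
    patients).  Genotypes are oriented to the population minor allele using
    a reference-population alternate-allele-frequency table, variant allele
    frequencies for both patient groups and the reference population are
    assembled into a three-column contingency table, variants are embedded
    and clustered by factorial correspondence analysis followed by
    hierarchical clustering on principal components, and genes are ranked
    by a bootstrap-replicated odds-ratio statistic fed into a two-class
    rank-product test with permutation-based percentage-of-false-prediction
    estimates.  A synthetic-cohort simulator with Hardy-Weinberg genotypes
    and controllable enrichment odds ratios supports end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    GenomicRanges,
    SummarizedExperiment,
    testthat (>= 3.0.0),
    VariantAnnotation,
    withr
Config/testthat/edition: 3
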