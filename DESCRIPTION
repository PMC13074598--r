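Package: transplantTraits
Title: Leaf Trait Analysis for Reciprocal Transplant Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the trait-based analysis of paired reciprocal transplant
    designs in contrasting light habitats. Derives structural, physiological and
    biochemical leaf traits from raw assay readings (leaf geometry, pigment and
    enzyme spectrophotometry, standard curves), computes the ODAC composite
    oxidative-balance index with within-habitat or global min-max normalization,
    quantifies phenotypic plasticity with the Valladares PI_V index, and runs the
    "home vs. away" / "local vs. foreign" statistical framework (balanced one-
    and two-way ANOVA, variance-ratio F-test, exact Wilcoxon rank-sum, Pearson
    and Spearman correlation, standardized regression, permutation Mantel test)
    implemented from first principles. A seeded synthetic-data generator emulates
    the paired two-population by two-habitat genotype design so the whole
    pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
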