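Package: agevar
Title: Meta-Analysis of Age-Related Gene Expression Heterogeneity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects age-related changes in inter-individual gene expression
    heterogeneity across multiple transcriptome datasets, separately for
    postnatal development and aging. Per gene and dataset, expression change is
    the slope of scaled log2 expression on fourth-root age and heterogeneity
    change is the Spearman correlation between absolute regression residuals
    and age. A dependence-aware permutation scheme (ages shuffled among
    individuals, not samples, so region datasets sharing donors stay coupled)
    provides nulls for cross-dataset consistency counts, period-difference
    tests, and independent-subset correlation tests. Includes trajectory
    clustering of heterogeneity profiles, preranked gene set enrichment with a
    tie-robustness procedure, downstream association tests (regulator counts,
    interaction-network degree, cell-type specificity and deconvolution, sex
    effects), a seeded synthetic-data generator, and an end-to-end pipeline
    runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    fgsea,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    limma,
    lmtest,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
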