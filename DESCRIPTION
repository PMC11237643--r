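Package: soilfp
Title: Genomic Fingerprints of Soil Microbiomes Along Environmental Gradients
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers "genomic fingerprints" of soil microbiomes from
    sample-by-attribute metagenomic count tables (KEGG orthologies, Pfam and
    TIGRFAM protein families, or read-based genera) and per-sample soil
    metadata. Provides attribute-type-specific read-count and prevalence
    filters, trimmed-mean-of-M-values (TMM) normalization, supervised
    fingerprint extraction (extreme-decile splits, random-forest permutation
    importance, structural-change breakpoint segmentation, signed
    least-squares slopes), a repeated cross-validation model-quality gate,
    unsupervised fingerprint extraction (k-means clustering with silhouette
    selection and per-cluster environmental regressions), and a synthetic
    count-table generator with planted signal for end-to-end recovery
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    cluster,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    ranger,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    edgeR,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
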