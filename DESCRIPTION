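Package: plastitox
Title: Toxicogenomic Screening of Plastic Additives
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for screening plastic additives for
    carcinogenic potential from public toxicogenomic data. Harmonizes
    IARC and EPA IRIS carcinogenicity classifications over a CAS-keyed
    additive registry, processes chemical-gene interaction tables with
    ortholog remapping to human Entrez identifiers, performs gene-set
    over-representation analysis with an enrichment-ratio statistic and
    Benjamini-Hochberg false discovery rate control, clusters additives
    on their pathway enrichment profiles through a silhouette-gated
    PCA/UMAP/k-means grid search, characterizes clusters by their
    differentially, uniquely and highly enriched cancer pathways, and
    quantifies gene- and pathway-level overlap between additives of
    unknown carcinogenicity and confirmed carcinogens. Includes a
    synthetic-data generator with planted cluster structure so that the
    whole pipeline is testable without database downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    uwot,
    withr
Suggests:
    cluster,
    jsonlite,
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
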