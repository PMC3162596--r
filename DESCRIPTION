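Package: crosstx
Title: Cross-Species Tissue Transcriptome Comparison by Enrichment Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A pipeline for comparing bulk tissue transcriptomes within and
    across species. Quantifies transcript abundance as RPKM from read-count
    tables, selects tissue-enriched genes with a one-sample t-statistic
    against a panel of comparison tissues, projects gene lists and expression
    matrices across species through Unigene-style homology maps, performs GO
    slim classification with hypergeometric and EASE over-representation
    statistics and transcriptional energy summaries, and scores tissue
    relatedness with a preranked running-sum gene-set enrichment statistic
    (permutation NES and FDR), producing a query-tissue by target-tissue
    relatedness matrix. Includes a seeded synthetic-data generator with
    planted tissue-enriched modules so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
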