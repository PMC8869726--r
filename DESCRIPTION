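Package: triadyn
Title: Time-Series Expression Dynamics and Homoeolog Bias in Polyploid
    Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for time-series RNA-seq of hexaploid wheat
    grain development: FPKM normalization and sample-level quality control,
    negative-binomial Wald tests for differential expression between
    adjacent developmental time points, co-expression clustering of
    differentially expressed genes by k-means under Pearson-correlation
    distance with silhouette-based selection of k, nearest-centroid
    classification of subgenome triads into seven homoeolog
    expression-bias categories with ternary coordinates and temporal
    transition tracking, and Fisher's exact test term over-representation.
    Includes a synthetic-data generator that plants bias categories,
    temporal co-expression profiles, differential expression, and enriched
    annotation terms with full ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    optparse
Config/testthat/edition: 3
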