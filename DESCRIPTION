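Package: clinmicro
Title: Clinical Microbiome Downstream Analysis and Regrouping Toolkit
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Downstream analysis of 16S relative-abundance tables in clinical
    cohorts: alignment of abundance tables to QIIME-style mapping files,
    clinical meta-data summaries and subject regrouping by a cluster-validity
    vote over mixed dietary/clinical variables, abundance/prevalence core-taxon
    filtering, alpha and Bray-Curtis beta diversity with PCoA and permutational
    MANOVA, per-group Spearman co-occurrence networks with graph statistics,
    repeated-seed random-forest cross-validation for biomarker union selection
    with pooled-CV ROC, and taxa-metadata correlation. Includes a synthetic
    compositional data generator with planted structure for end-to-end testing
    and a one-step pipeline runner with a JSON manifest.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    cluster,
    vegan,
    igraph,
    randomForest,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
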