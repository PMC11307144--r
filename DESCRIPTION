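Package: icibiome
Title: Intratumoral Microbiome and Immune Gene Signatures for
    Immunotherapy Response Prediction
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Links tumor RNA-seq-derived intratumoral microbe abundances
    and host immune gene-expression signatures to immune-checkpoint-
    inhibitor (ICI) response in melanoma. Provides readers for expression
    (TPM), microbe count and GMT gene-set formats; a synthetic-cohort
    generator with planted immune and microbial effects; descriptive
    cohort statistics; signature Z-scoring with Mann-Whitney testing and
    AUROC evaluation; single-sample and two-class gene-set enrichment
    with gene-set permutation; alpha-diversity estimators and a
    negative-binomial Wald differential-abundance test; Spearman
    microbe-signature correlation with hierarchical ordering; and a
    random-forest cross-validation harness that combines microbe and
    signature features into a response classifier with external
    validation by balanced accuracy.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    vegan,
    randomForest,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    fgsea,
    DESeq2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
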