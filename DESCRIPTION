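Package: melresist
Title: Immunogenomic Analysis of Immune-Checkpoint-Inhibitor Resistance in Melanoma
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested re-implementation of an immunogenomic analysis workflow
    for immune checkpoint inhibitor (ICI) resistance in adolescent and young
    adult (AYA) melanoma. Provides directed rank-based single-sample gene
    signature scoring (YIM/IPRES/IMMU-style), differential-expression-driven
    signature construction over negative-binomial counts, immunophenogram
    category profiling, a somatic-variant filter cascade with MAF emission,
    peritumor/intratumor multiplex-immunofluorescence cell-density
    quantification, exact contingency-table and rank-based outcome statistics
    with survival comparison and ROC evaluation, and druggable-target
    matching. A synthetic cohort generator reproduces the statistical
    structure every stage assumes, so the whole pipeline is exercised without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    survival,
    yaml
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    SummarizedExperiment,
    pROC,
    vcfR
Config/testthat/edition: 3
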