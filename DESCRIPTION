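Package: sncfrag
Title: Hierarchical Annotation and Biomarker Analysis of Circulating Small
    Non-Coding RNA Fragments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for profiling 15-45 nt small non-coding RNA (sncRNA)
    fragments in cell-free compartments such as serum and bone-marrow
    supernatant. Reads are collapsed and assigned to sncRNA classes (miRNA,
    rRNA-, tRNA-, and YRNA-derived fragments, piRNA, other ncRNA) by
    hierarchical exact matching against a curated parental-RNA reference;
    fragments are characterized by cleavage subtype (5', inner', 3', 3'CCA
    tsRNAs), positional coverage and peak calling on rRNA parents, and
    YRNA gene composition. Downstream stages provide trimmed-mean
    normalization, a negative-binomial conditional exact test for
    case-control differential expression, three-criterion marker-panel
    selection with bagged-tree classification (out-of-bag error, ROC/AUC),
    and paired blood/bone-marrow concordance. A self-contained synthetic
    reference and cohort generator with known ground truth supports
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    randomForest,
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
    testthat (>= 3.0.0)
Config/testthat/edition: 3
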