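Package: metadriver
Title: Signal-Based Discovery of Metastasis Driver Modules from Tumor Genomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Discovers candidate driver modules of metastasis by combining
    transcriptomic and somatic-alteration evidence. Differentially expressed
    genes are called along a metastatic cell-line lineage by fold change and
    refined against lung-tumor cohorts; for each transcription factor a dense
    gene-by-tumor quasi-biclique (a transcriptomic module) is mined from the
    tumor dysregulation matrix, partitioning tumors into module-abnormal and
    module-normal sets; somatic mutations and expression-concordant copy-number
    events are collapsed into a binary alteration matrix; and a genetic
    algorithm searches the enrichment-filtered candidate genes for small gene
    sets whose alterations are mutually exclusive and maximally enriched in the
    module-abnormal tumors, scored by an exact hypergeometric tail probability.
    Includes a synthetic-data generator that emulates every input with planted
    ground truth, so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
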