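Package: methylscreen
Title: Epigenome-Wide Methylation-Drug-Response Association Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for epigenome-wide association of Illumina
    EPIC-style DNA methylation with pharmacological response in cancer cell
    line panels. Provides probe quality control (detection p-value masking,
    median detection-p and SNP-mask probe removal), gene-region averaging of
    beta-values over the six manifest region classes, Spearman correlation of
    probe- and region-level methylation with median log(IC50) under fixed
    probe thresholds and Benjamini-Hochberg false-discovery-rate families,
    integration with transcript expression, copy number and lineage-marker
    clustering, and a synthetic-data generator with planted effects for
    end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    ape,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
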