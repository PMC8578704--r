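Package: degrontime
Title: Time-Resolved Integration of Chromatin and Transcription Changes
    After Acute Protein Depletion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for integrating degron time-course multi-omics: classify
    the direction and earliest time of significant change for differential
    chromatin sites (ATAC-seq, ChIP-seq), link changed sites to gene promoter
    and enhancer windows, build gene cohorts and fold-change quintiles, score
    per-quintile enrichment with an exact log-space hypergeometric probability
    mass function, and compute nucleosome-midpoint metaprofiles around
    transcription-factor motifs with barrier-nucleosome spacing metrics.
    Includes a seeded synthetic-data generator with planted, recoverable
    structure for end-to-end validation.
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
    IRanges,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
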