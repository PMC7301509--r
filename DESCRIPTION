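Package: meshsimr
Title: MeSH Term Recognition, Normalization and Semantic Similarity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for working with the Medical Subject Headings (MeSH)
    controlled vocabulary: an in-memory five-table data model covering main
    headings (MHs) and supplementary concept records (SCRs), a builder for
    UMLS RRF-style pipe-delimited inputs, a deterministic synthetic fixture
    generator with identical schema, a dictionary-based recognizer that maps
    free biomedical phrases to MeSH terms (with MetaMap fielded-output
    ingestion, SCR-to-broader-heading expansion and recursive resolution of
    non-MeSH-synonymous concepts), information content computed from
    publication counts rolled up over hierarchy descendants, and five
    semantic-similarity measures between MeSH terms: Resnik, Lin,
    Jiang-Conrath, Schlicker and the graph-based Wang measure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr,
    stats,
    utils
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
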