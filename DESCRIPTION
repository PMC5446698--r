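Package: taxparse
Title: Semantic Parsing of Scientific Name-Strings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decomposes taxonomic name-strings into semantically labelled
    elements using a parsing expression grammar written for the structure of
    botanical, zoological and prokaryotic nomenclature. Renders canonical and
    normalized forms, position-annotated JSON documents with quality warnings,
    and deterministic UUID version 5 identifiers. Includes a pre-cleaning
    stage for common dataset corruptions, an evaluation harness computing
    precision, recall, accuracy and F1 against a gold standard, and a seeded
    synthetic corpus generator with corruption operators for end-to-end
    testing.
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
    rlang,
    stats,
    stringi,
    stringr,
    tibble,
    tidyr,
    utils,
    uuid
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
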