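Package: itermine
Title: Informative-Term Mining for Genes from Literature Abstracts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Retrieves and disambiguates literature abstracts for a gene,
    filters them to those that focus on the gene, and ranks informative
    terms (iTerms) by contrasting document frequencies in the gene's
    abstracts against a large generic gene/protein background corpus.
    Ambiguous gene names are resolved with per-sense bigram language
    models trained automatically on anchor abstracts and detected
    abbreviation-expansion pairs. Inflectional variants are pooled into
    lexemes before counting, ranked terms are assigned to display
    categories, and each term is linked to ranked evidence sentences.
    A seeded synthetic-corpus generator with known ground truth makes
    every stage testable without any external download.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    tibble,
    utils,
    xml2,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
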