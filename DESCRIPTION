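Package: litqa
Title: Question Answering over Titled Abstract Corpora
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An end-to-end question answering engine for corpora of titled
    abstracts (e.g. biomedical literature). Converts a natural-language
    question into a weighted boolean keyword query that is iteratively
    relaxed until documents are retrieved, ranks candidate answer sentences
    by an IDF-weighted relaxed word mover's distance over word and phrase
    embeddings, filters candidates by the question focus entity type using
    gazetteer lookup over nine biomedical entity types, optionally reranks
    with a trainable sentence-pair classifier, and extracts exact answer
    phrases for factoid questions. Includes collocation-based phrase mining,
    a deterministic rule-based linguistic annotator, a sequence-labelling
    keyword selector, mean-reciprocal-rank evaluation utilities, and a
    seeded synthetic fixture generator so the whole pipeline is testable
    offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
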