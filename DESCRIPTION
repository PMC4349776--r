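Package: termenrich
Title: Headword-Based Term Extraction for Enriching Biomedical Vocabularies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts candidate biomedical noun phrases from abstracts using
    headword-anchored chunking and three lexico-syntactic patterns (headword
    removal with in-abstract verification, appositive definitions, and
    "is/are/as a" hyponymy templates), then filters the candidates with a
    linear classifier trained on character n-gram features using the modified
    Huber loss. Includes a bigram-compatibility test of vocabulary terms
    against a corpus, a pluggable part-of-speech tagger contract with a
    built-in rule tagger, seeded generators for synthetic corpora and
    vocabularies, and an end-to-end pipeline that separates newly discovered
    terms from those already present in a controlled vocabulary.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
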