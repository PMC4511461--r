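Package: ontohab
Title: Rule-Based Recognition and Ontology Normalization of Bacteria
    Habitat Mentions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects mentions of bacteria habitats in plain text by shallow
    syntactic analysis (sentence segmentation, part-of-speech tagging,
    lemmatization and noun-phrase chunking), normalizes them to concepts of
    an OBO-format habitat ontology, and extracts bacterium-habitat
    Localization and habitat-habitat PartOf relations with a rule-based
    anaphora resolver.  Includes a reader and writer for the BioNLP-ST
    standoff annotation dialect (.txt/.a1/.a2) with discontinuous spans,
    ontology expansion from annotated training data, and a Slot Error Rate
    (SER) scorer that combines span overlap with ancestor-set concept
    similarity under an optimal one-to-one entity pairing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
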