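# Shared fixture objects, built once per test run.
fixture_ont <- build_fixture_ontology()
fixture_docs <- build_fixture_documents()

analyze_fixture <- local({
  cache <- new.env(parent = emptyenv())
  function(id) {
    if (is.null(cache[[id]])) {
      cache[[id]] <- analyze(fixture_docs[[id]]$doc$text)
    }
    cache[[id]]
  }
})

# Candidate phrase for the (first) simplified NP of a sentence that contains
# a given word, convenience for boundary/coordination tests.
candidate_containing <- function(adoc, word) {
  for (sentence in adoc$sentences) {
    nps <- extract_noun_phrases(sentence)
    for (r in seq_len(nrow(nps))) {
      cand <- simplify_noun_phrase(nps[r, ], sentence)
      if (!is.null(cand) && word %in% tolower(cand$surface)) {
        return(list(candidate = cand, sentence = sentence))
      }
    }
  }
  stop("no candidate containing: ", word)
}

relations_of <- function(id, partof = TRUE) {
  fx <- fixture_docs[[id]]
  adoc <- analyze_fixture(id)
  rels <- if (fx$strategy == "sentence") {
    extract_sentence_based(adoc, fx$doc$entities)
  } else {
    extract_paragraph_based(adoc, fx$doc$entities)
  }
  if (partof) rels <- rbind(rels, extract_partof(fx$doc$entities, adoc))
  unique(rels)
}

expect_same_relations <- function(pred, gold) {
  canon <- function(d) {
    d <- d[c("rtype", "arg1", "arg2")]
    d[order(d$rtype, d$arg1, d$arg2), ]
  }
  p <- canon(pred); g <- canon(gold)
  row.names(p) <- row.names(g) <- NULL
  expect_equal(p, g)
}
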