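test_that("specific-bacteria filtering is case-insensitive on generic terms", {
  mk <- function(text) {
    entity_ref("T1", "Bacteria", ontohab:::new_fragments(0L, nchar(text)), text)
  }
  expect_true(is_specific_bacteria(mk("Bordetella petrii DSM12804")))
  expect_false(is_specific_bacteria(mk("bacterium")))
  expect_false(is_specific_bacteria(mk("Bacteria")))
  hab <- entity_ref("T2", "Habitat", ontohab:::new_fragments(0L, 3L), "gut")
  expect_error(is_specific_bacteria(hab), "Bacteria entity")
})

test_that("anaphora resolution handles the three anaphor types", {
  # type 1: listed expression, antecedent from the previous sentence
  fx <- fixture_docs$`brucella-canis`
  adoc <- analyze_fixture("brucella-canis")
  ante <- resolve_anaphora(adoc$sentences[[2]], adoc, fx$doc$entities)
  expect_equal(ante$text, "Brucella canis")
  # type 2: sentence-initial "it"
  fx <- fixture_docs$`borrelia-burgdorferi`
  adoc <- analyze_fixture("borrelia-burgdorferi")
  ante <- resolve_anaphora(adoc$sentences[[2]], adoc, fx$doc$entities)
  expect_equal(ante$text, "Borrelia burgdorferi")
  # type 3: "This strain" -> first bacteria entity of the document
  fx <- fixture_docs$`strain-feces`
  adoc <- analyze_fixture("strain-feces")
  ante <- resolve_anaphora(adoc$sentences[[2]], adoc, fx$doc$entities)
  expect_equal(ante$text, "Bifidobacterium longum NCC2705")
  # no anaphor -> no antecedent
  fx <- fixture_docs$`partof-rules`
  adoc <- analyze_fixture("partof-rules")
  expect_null(resolve_anaphora(adoc$sentences[[1]], adoc, fx$doc$entities))
})

test_that("type-1 resolution falls back to the document-first bacterium", {
  text <- "Brucella canis.\n\nSoil samples were described.\n\nThis organism lives in water.\n"
  adoc <- analyze(text)
  ents <- list(
    entity_ref("T1", "Bacteria", span_of(text, "Brucella canis"), "Brucella canis"),
    entity_ref("T2", "Habitat", span_of(text, "water"), "water"))
  # the previous sentence has no bacteria entity -> first in document
  ante <- resolve_anaphora(adoc$sentences[[3]], adoc, ents)
  expect_equal(ante$id, "T1")
  rels <- extract_sentence_based(adoc, ents)
  expect_same_relations(rels, data.frame(rtype = "Localization",
                                         arg1 = "T1", arg2 = "T2"))
  # type 2 has no such fallback
  text2 <- "Brucella canis.\n\nSoil samples were described.\n\nIt lives in water.\n"
  adoc2 <- analyze(text2)
  ents2 <- list(
    entity_ref("T1", "Bacteria", span_of(text2, "Brucella canis"), "Brucella canis"),
    entity_ref("T2", "Habitat", span_of(text2, "water"), "water"))
  expect_null(resolve_anaphora(adoc2$sentences[[3]], adoc2, ents2))
})

test_that("paragraph strategy anchors on the first (strain-corrected) bacterium", {
  fx <- fixture_docs$`bordetella-petrii`
  adoc <- analyze_fixture("bordetella-petrii")
  rels <- extract_paragraph_based(adoc, fx$doc$entities)
  # anchored to the earlier strain-less mention, not the in-paragraph one
  expect_same_relations(rels, data.frame(rtype = "Localization",
                                         arg1 = "T2", arg2 = "T4"))
  # one bacterium, two habitats in a paragraph -> two relations
  fx2 <- fixture_docs$`bordetella-group`
  adoc2 <- analyze_fixture("bordetella-group")
  rels2 <- extract_paragraph_based(adoc2, fx2$doc$entities)
  expect_equal(nrow(rels2), 2L)
  expect_setequal(rels2$arg2, c("T2", "T3"))
  # habitats with no bacteria anywhere -> nothing
  text <- "Samples of water.\n"
  adoc3 <- analyze(text)
  ents <- list(entity_ref("T1", "Habitat", span_of(text, "water"), "water"))
  expect_equal(nrow(extract_paragraph_based(adoc3, ents)), 0L)
})

test_that("sentence strategy pairs specific bacteria and resolved anaphors", {
  for (id in c("brucella-canis", "borrelia-burgdorferi", "strain-feces",
               "bordetella-group", "bifidobacterium", "partof-rules")) {
    expect_same_relations(relations_of(id), fixture_docs[[id]]$doc$relations)
  }
  # with anaphora fully disabled the extractor is pure same-sentence
  # co-occurrence: the anaphoric documents yield nothing
  empty_cfg <- anaphora_config(type1_expressions = character(),
                               type2_pronoun = character(),
                               type3_prefix = character())
  for (id in c("brucella-canis", "borrelia-burgdorferi", "strain-feces")) {
    fx <- fixture_docs[[id]]
    rels <- extract_sentence_based(analyze_fixture(id), fx$doc$entities,
                                   empty_cfg)
    expect_equal(nrow(rels), 0L, info = id)
  }
  # ... while purely in-sentence documents are unaffected
  fx <- fixture_docs$`partof-rules`
  expect_same_relations(
    extract_sentence_based(analyze_fixture("partof-rules"), fx$doc$entities,
                           empty_cfg),
    fx$doc$relations[fx$doc$relations$rtype == "Localization", ])
})

test_that("paragraph and sentence strategies agree on one-sentence documents", {
  text <- "Pseudomonas fluorescens lives in the rhizosphere of plants.\n"
  adoc <- analyze(text)
  ents <- list(
    entity_ref("T1", "Bacteria", span_of(text, "Pseudomonas fluorescens"),
               "Pseudomonas fluorescens"),
    entity_ref("T2", "Habitat", span_of(text, "rhizosphere of plants"),
               "rhizosphere of plants"),
    entity_ref("T3", "Habitat", span_of(text, "plants"), "plants"))
  a <- extract_paragraph_based(adoc, ents)
  b <- extract_sentence_based(adoc, ents)
  expect_same_relations(a, b)
})

test_that("PartOf rules fire on containment with preposition or prefix", {
  fx <- fixture_docs$`partof-rules`
  adoc <- analyze_fixture("partof-rules")
  po <- extract_partof(fx$doc$entities, adoc)
  expect_same_relations(po, fx$doc$relations[fx$doc$relations$rtype == "PartOf", ])
  # disjoint habitats yield nothing
  text <- "Water and soil.\n"
  adoc2 <- analyze(text)
  ents <- list(entity_ref("T1", "Habitat", span_of(text, "Water"), "Water"),
               entity_ref("T2", "Habitat", span_of(text, "soil"), "soil"))
  expect_equal(nrow(extract_partof(ents, adoc2)), 0L)
})

test_that("extracted relations respect the type constraints", {
  for (id in names(fixture_docs)) {
    fx <- fixture_docs[[id]]
    if (fx$task != "relations") next
    adoc <- analyze_fixture(id)
    rels <- relations_of(id)
    ents <- fx$doc$entities
    etype <- stats::setNames(vapply(ents, `[[`, "", "etype"),
                             vapply(ents, `[[`, "", "id"))
    loc <- rels[rels$rtype == "Localization", ]
    expect_true(all(etype[loc$arg1] == "Bacteria"))
    expect_true(all(etype[loc$arg2] %in% c("Habitat", "Geographical")))
    po <- rels[rels$rtype == "PartOf", ]
    expect_true(all(etype[c(po$arg1, po$arg2)] == "Habitat"))
    expect_true(all(rels$arg1 != rels$arg2))
  }
})
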