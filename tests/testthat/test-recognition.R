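test_that("noun-phrase simplification drops determiners and possessives", {
  cases <- list(
    list(text = "The mummy tissue was sampled.", keep = c("mummy", "tissue")),
    list(text = "Bacteria reached its small intestine.",
         keep = c("small", "intestine")),
    list(text = "Samples contained water.", keep = "water"))
  for (cs in cases) {
    adoc <- analyze(cs$text)
    sent <- adoc$sentences[[1]]
    nps <- extract_noun_phrases(sent)
    cands <- Filter(Negate(is.null), lapply(seq_len(nrow(nps)), function(r) {
      simplify_noun_phrase(nps[r, ], sent)
    }))
    surfaces <- lapply(cands, function(cd) tolower(cd$surface))
    expect_true(any(vapply(surfaces, identical, NA, tolower(cs$keep))),
                info = cs$text)
  }
  # an NP of only removable tokens vanishes
  sent <- analyze("The the.")$sentences[[1]]
  nps <- extract_noun_phrases(sent)
  if (nrow(nps)) {
    expect_null(simplify_noun_phrase(nps[1, ], sent))
  }
})

test_that("coordination splitting applies shared-head completion", {
  cases <- list(
    list(word = "pharyngeal", doc = "coordination",
         sub1 = c("pharyngeal", "mucosa"), sub2 = c("gut", "mucosa")),
    list(word = "iron-rich", doc = "coordination",
         sub1 = c("iron-rich", "environment"), sub2 = c("wet", "environment")),
    list(word = "plants", doc = "coordination",
         sub1 = "plants", sub2 = "animals"),
    list(word = "mouse", doc = "coordination",
         sub1 = "mouse", sub2 = "cheese"))
  for (cs in cases) {
    got <- candidate_containing(analyze_fixture(cs$doc), cs$word)
    sp <- split_coordination(got$candidate, got$sentence)
    expect_equal(tolower(sp$sub1$surface), cs$sub1, info = cs$word)
    expect_equal(tolower(sp$sub2$surface), cs$sub2, info = cs$word)
  }
  # no "and" -> no split; degenerate first/last "and" -> no split
  got <- candidate_containing(analyze_fixture("mummy-tissue"), "mummy")
  expect_null(split_coordination(got$candidate, got$sentence))
  sent <- analyze("Water and soil.")$sentences[[1]]
  lead_and <- ontohab:::candidate_phrase(sent, 2:3)   # "and soil"
  expect_null(split_coordination(lead_and, sent))
  trail_and <- ontohab:::candidate_phrase(sent, 1:2)  # "Water and"
  expect_null(split_coordination(trail_and, sent))
})

test_that("ontology matching finds exact, prefix and internal partial matches", {
  got <- candidate_containing(analyze_fixture("bodily-fluid"), "fluid")
  m <- match_ontology(got$candidate, fixture_ont)
  m <- m[order(m$first), ]
  expect_equal(nrow(m), 2L)
  expect_equal(m$concept_id, c("MBTO:00001660", "MBTO:00000921"))
  expect_equal(m$kind, c("prefix_partial", "internal_partial"))
  expect_equal(m$first, c(1L, 2L))
  expect_equal(m$last, c(1L, 3L))

  got <- candidate_containing(analyze_fixture("mummy-tissue"), "mummy")
  m <- match_ontology(got$candidate, fixture_ont)
  expect_equal(m$kind, "exact")
  expect_equal(m$concept_id, "MBTO:00001875")

  # lemma matching: plural "animals" finds the singular label
  got <- candidate_containing(analyze_fixture("coordination"), "animals")
  sp <- split_coordination(got$candidate, got$sentence)
  m <- match_ontology(sp$sub2, fixture_ont)
  expect_equal(m$concept_id, "MBTO:00001660")
  expect_equal(m$via, "lemma")
  off <- match_ontology(sp$sub2, fixture_ont,
                        recognition_config(lemma_matching = FALSE))
  expect_equal(nrow(off), 0L)
})

test_that("boundary rules set spans per match kind and merge identical spans", {
  got <- candidate_containing(analyze_fixture("bodily-fluid"), "fluid")
  adoc <- analyze_fixture("bodily-fluid")
  m <- match_ontology(got$candidate, fixture_ont)
  mentions <- apply_boundary_rules(got$candidate, m, got$sentence, adoc$text)
  texts <- vapply(mentions, `[[`, "", "text")
  expect_setequal(texts, c("animal", "animal bodily fluid"))
  expect_equal(mentions[[which(texts == "animal")]]$concept_ids, "MBTO:00001660")
  expect_equal(mentions[[which(texts == "animal bodily fluid")]]$concept_ids,
               "MBTO:00000921")
  # two internal matches on one candidate merge into a two-concept mention
  tiny <- obo_ontology(list(obo_concept("X:1", "beta"),
                            obo_concept("X:2", "gamma")))
  adoc2 <- analyze("Some alpha beta gamma here.")
  got2 <- candidate_containing(adoc2, "beta")
  m2 <- match_ontology(got2$candidate, tiny)
  expect_setequal(m2$kind, "internal_partial")
  merged <- apply_boundary_rules(got2$candidate, m2, got2$sentence, adoc2$text)
  expect_length(merged, 1L)
  expect_setequal(merged[[1]]$concept_ids, c("X:1", "X:2"))
})

test_that("coordination resolution follows the common-direct-parent rule", {
  adoc <- analyze_fixture("coordination")
  resolve <- function(word) {
    got <- candidate_containing(adoc, word)
    sp <- split_coordination(got$candidate, got$sentence)
    resolve_coordination(sp$sub1, sp$sub2, got$candidate, fixture_ont,
                         got$sentence, adoc$text)
  }
  # no common direct parent -> two entities, the first discontinuous
  m <- resolve("pharyngeal")
  expect_length(m, 2L)
  expect_equal(m[[1]]$text, "pharyngeal mucosa")
  expect_equal(nrow(m[[1]]$fragments), 2L)
  expect_equal(m[[2]]$text, "gut mucosa")
  # common direct parent, multiword -> one entity with both concepts
  m <- resolve("iron-rich")
  expect_length(m, 1L)
  expect_equal(m[[1]]$text, "iron-rich and wet environment")
  expect_setequal(m[[1]]$concept_ids,
                  c(label_lookup(fixture_ont, "iron-rich environment"),
                    label_lookup(fixture_ont, "wet environment")))
  # common direct parent but two single nouns -> two entities
  m <- resolve("plants")
  expect_length(m, 2L)
  expect_setequal(vapply(m, `[[`, "", "text"), c("plants", "animals"))
  # disjoint parents -> two entities
  m <- resolve("mouse")
  expect_length(m, 2L)
  expect_setequal(vapply(m, `[[`, "", "text"), c("mouse", "cheese"))
})

test_that("modifier attachment is opt-in and emits merged candidates", {
  adoc <- analyze_fixture("infant-germany")
  # off by default: no mention crosses a preposition token
  default <- detect_entities(adoc, fixture_ont)
  for (m in default) expect_false(grepl("\\bin\\b", m$text))
  # enabled: the NP-prep-NP candidate maps via the internal-match rule to the
  # full phrase, normalized to the head concept of the first NP
  on <- detect_entities(adoc, fixture_ont,
                        recognition_config(modifier_preps = "in"))
  texts <- vapply(on, `[[`, "", "text")
  expect_true("infected infant in Germany" %in% texts)
  expect_equal(on[[which(texts == "infected infant in Germany")]]$concept_ids,
               "MBTO:00000778")
  # a sentence with no preposition between NPs is unchanged
  adoc2 <- analyze_fixture("mummy-tissue")
  expect_equal(detect_entities(adoc2, fixture_ont,
                               recognition_config(modifier_preps = "in")),
               detect_entities(adoc2, fixture_ont))
})

test_that("document-level detection is ordered, deduplicated and well-formed", {
  adoc <- analyze_fixture("coordination")
  mentions <- detect_entities(adoc, fixture_ont)
  starts <- vapply(mentions, function(m) m$fragments$start[1], 0L)
  expect_false(is.unsorted(starts))
  for (m in mentions) {
    expect_true(all(m$concept_ids %in% names(fixture_ont$concepts)))
    expect_true(all(m$fragments$end <= nchar(adoc$text)))
    expect_gt(length(m$concept_ids), 0)
  }
  # a document whose NPs match nothing yields no mentions
  none <- detect_entities(analyze("Severe diseases were observed.\n"), fixture_ont)
  expect_length(none, 0L)
  # disabling coordination changes nothing for texts without "and" in an NP
  for (id in c("bodily-fluid", "mummy-tissue")) {
    a <- analyze_fixture(id)
    expect_equal(detect_entities(a, fixture_ont,
                                 recognition_config(coordination = FALSE)),
                 detect_entities(a, fixture_ont))
  }
})
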