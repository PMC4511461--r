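test_that("OBO parsing builds a queryable, label-indexed ontology", {
  obo <- c(
    "format-version: 1.2", "",
    "[Term]", "id: MBTO:00001875", "name: mummy tissue", "",
    "[Term]", "id: MBTO:00000921", "name: body fluid",
    'synonym: "bodily fluid" EXACT []', "",
    "[Term]", "id: MBTO:00000001", "name: old thing",
    "is_a: MBTO:00001875 ! mummy tissue", "is_obsolete: true", "")
  ont <- parse_obo(obo)
  expect_equal(label_lookup(ont, "mummy tissue"), "MBTO:00001875")
  expect_equal(label_lookup(ont, "body fluid"), "MBTO:00000921")
  expect_equal(label_lookup(ont, "bodily fluid"), "MBTO:00000921")
  # obsolete terms are retained in the concept map but not indexed
  expect_true("MBTO:00000001" %in% names(ont$concepts))
  expect_length(label_lookup(ont, "old thing"), 0)
  # empty stream
  empty <- parse_obo(character())
  expect_length(empty$concepts, 0)
  expect_equal(nrow(empty$label_index), 0L)
})

test_that("malformed or inconsistent OBO input is rejected with diagnostics", {
  expect_error(parse_obo(c("[Term]", "id: MBTO:1")), "no name")
  expect_error(parse_obo(c("[Term]", "name: orphan")), "no id")
  expect_error(
    parse_obo(c("[Term]", "id: A", "name: a", "is_a: MISSING")),
    "MISSING")
  expect_error(
    parse_obo(c("[Term]", "id: A", "name: a", "is_a: B",
                "", "[Term]", "id: B", "name: b", "is_a: A")),
    "cycle")
  expect_error(
    parse_obo(c("[Term]", "id: A", "name: a",
                "", "[Term]", "id: A", "name: a2")),
    "duplicate")
})

test_that("direct parents follow the fixture is_a structure", {
  gm <- label_lookup(fixture_ont, "gut mucosa")
  pm <- label_lookup(fixture_ont, "pharyngeal mucosa")
  expect_setequal(
    direct_parents(fixture_ont, gm),
    c(label_lookup(fixture_ont, "digestive tract part"),
      label_lookup(fixture_ont, "mucosal tissue")))
  expect_equal(direct_parents(fixture_ont, pm),
               label_lookup(fixture_ont, "respiratory tract part"))
  root <- label_lookup(fixture_ont, "habitat")
  expect_length(direct_parents(fixture_ont, root), 0)
  expect_error(direct_parents(fixture_ont, "MBTO:99999999"), "unknown")
})

test_that("ancestor closure handles chains, diamonds and self-inclusion", {
  chain <- obo_ontology(list(
    obo_concept("C", "c"), obo_concept("B", "b", parents = "C"),
    obo_concept("A", "a", parents = "B")))
  expect_setequal(ancestors(chain, "A"), c("B", "C"))
  expect_equal(ancestors(chain, "C", include_self = TRUE), "C")
  diamond <- obo_ontology(list(
    obo_concept("D", "d"),
    obo_concept("B", "b", parents = "D"), obo_concept("C", "c", parents = "D"),
    obo_concept("A", "a", parents = c("B", "C"))))
  expect_setequal(ancestors(diamond, "A"), c("B", "C", "D"))
})

test_that("ancestor computation agrees with a brute-force DFS oracle", {
  set.seed(41)
  for (rep in 1:20) {
    ont <- random_dag_ontology(sample(5:50, 1))
    for (id in sample(names(ont$concepts), 5)) {
      expect_identical(ancestors(ont, id), brute_ancestors(ont, id))
      expect_true(all(direct_parents(ont, id) %in%
                        ancestors(ont, id, include_self = FALSE)))
      expect_true(all(ancestors(ont, id) %in%
                        ancestors(ont, id, include_self = TRUE)))
    }
  }
})

test_that("ontology expansion adds unseen surface forms as exact synonyms", {
  ann <- fixture_training_annotations()
  ex <- expand_from_annotations(fixture_ont, ann)
  expect_equal(label_lookup(ex, "tissues of ancient mummies"), "MBTO:00001875")
  expect_equal(label_lookup(ex, "gut of mice"),
               label_lookup(fixture_ont, "gut mucosa"))
  # "mummy tissue" is already the concept name: not added again
  expect_equal(sum(ex$label_index$id == "MBTO:00001875"), 2L)
  added <- attr(ex, "added")
  expect_false("mummy tissue" %in% added$added_synonym)
  # input untouched; empty annotation list is the identity
  expect_length(label_lookup(fixture_ont, "tissues of ancient mummies"), 0)
  same <- expand_from_annotations(
    fixture_ont, data.frame(surface_text = character(), concept_id = character()))
  expect_equal(same$label_index, fixture_ont$label_index)
  expect_error(
    expand_from_annotations(fixture_ont, data.frame(
      surface_text = "x", concept_id = "MBTO:12345678")),
    "MBTO:12345678")
})

test_that("expansion is idempotent", {
  ann <- fixture_training_annotations()
  once <- expand_from_annotations(fixture_ont, ann)
  twice <- expand_from_annotations(once, ann)
  expect_equal(twice$label_index, once$label_index)
  expect_equal(nrow(attr(twice, "added")), 0L)
})

test_that("parse -> serialize -> parse round-trips the ontology", {
  set.seed(42)
  onts <- c(list(fixture_ont), lapply(1:5, function(i) random_dag_ontology(15)))
  for (ont in onts) {
    back <- parse_obo(write_obo(ont))
    expect_setequal(names(back$concepts), names(ont$concepts))
    for (id in names(ont$concepts)) {
      expect_setequal(back$concepts[[id]]$parents, ont$concepts[[id]]$parents)
      expect_equal(back$concepts[[id]]$name, ont$concepts[[id]]$name)
      expect_setequal(back$concepts[[id]]$exact_synonyms,
                      ont$concepts[[id]]$exact_synonyms)
    }
  }
})
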