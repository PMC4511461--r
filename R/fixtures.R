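# Packaged fixture bundle: a mini habitat ontology and a set of small
# standoff documents exercising every recognition and relation-extraction
# rule, so the full pipeline runs and is scoreable offline.  Concept ids not
# established in the ontology release are drawn from the reserved synthetic
# range MBTO:0990xxxx and flagged in the manifest.

fixture_concept_table <- function() {
  # name | id | exact synonyms | parents (by name) | synthetic id?
  list(
    list("habitat",                              "MBTO:09900001", character(), character(), TRUE),
    list("living organism",                      "MBTO:09900002", character(), "habitat", TRUE),
    list("eukaryote host",                       "MBTO:09900003", character(), "living organism", TRUE),
    list("plant",                                "MBTO:09900004", character(), "eukaryote host", TRUE),
    list("animal",                               "MBTO:00001660", character(), "eukaryote host", FALSE),
    list("mouse",                                "MBTO:09900005", character(), "animal", TRUE),
    list("human",                                "MBTO:09900006", character(), "animal", TRUE),
    list("infant",                               "MBTO:00000778", character(), "human", FALSE),
    list("host part",                            "MBTO:09900007", character(), "habitat", TRUE),
    list("respiratory tract part",               "MBTO:09900008", character(), "host part", TRUE),
    list("digestive tract part",                 "MBTO:09900009", character(), "host part", TRUE),
    list("mucosal tissue",                       "MBTO:09900010", character(), "host part", TRUE),
    list("pharyngeal mucosa",                    "MBTO:09900011", character(), "respiratory tract part", TRUE),
    list("gut mucosa",                           "MBTO:09900012", character(), c("digestive tract part", "mucosal tissue"), TRUE),
    list("respiratory tract",                    "MBTO:09900013", character(), "host part", TRUE),
    list("digestive tract",                      "MBTO:09900014", "gastrointestinal tract", "host part", TRUE),
    list("small intestine",                      "MBTO:09900015", character(), "digestive tract part", TRUE),
    list("habitat wrt chemico-physical property", "MBTO:09900016", character(), "habitat", TRUE),
    list("iron-rich environment",                "MBTO:09900017", character(), "habitat wrt chemico-physical property", TRUE),
    list("wet environment",                      "MBTO:09900018", character(), "habitat wrt chemico-physical property", TRUE),
    list("food",                                 "MBTO:09900019", character(), "habitat", TRUE),
    list("cheese",                               "MBTO:09900020", character(), "food", TRUE),
    list("mummy tissue",                         "MBTO:00001875", character(), "host part", FALSE),
    list("body fluid",                           "MBTO:00000921", "bodily fluid", "host part", FALSE)
  )
}

#' The packaged fixture ontology
#'
#' A ~24-concept habitat ontology (a DAG: "gut mucosa" has two is_a parents)
#' covering every concept the worked examples need: the coordination
#' examples, the "animal bodily fluid" mapping, and the
#' "human gastrointestinal tract" normalization to "digestive tract".
#'
#' @return an [obo_ontology()].
#' @export
build_fixture_ontology <- function() {
  tab <- fixture_concept_table()
  name2id <- stats::setNames(vapply(tab, `[[`, "", 2L),
                             vapply(tab, `[[`, "", 1L))
  obo_ontology(lapply(tab, function(row) {
    obo_concept(row[[2L]], row[[1L]], exact_synonyms = row[[3L]],
                parents = unname(name2id[row[[4L]]]))
  }))
}

#' Manifest of fixture concepts
#'
#' @return data.frame with `name`, `id` and `synthetic` (`TRUE` for ids drawn
#'   from the reserved MBTO:0990xxxx range rather than the ontology release).
#' @export
fixture_concept_manifest <- function() {
  tab <- fixture_concept_table()
  data.frame(name = vapply(tab, `[[`, "", 1L),
             id = vapply(tab, `[[`, "", 2L),
             synthetic = vapply(tab, `[[`, NA, 5L))
}

fixture_id <- function(name) {
  man <- fixture_concept_manifest()
  man$id[man$name == name]
}

#' Example training annotations for ontology expansion
#'
#' @return data.frame `surface_text`/`concept_id` in the shape produced by
#'   normalization lines of annotated training documents.
#' @export
fixture_training_annotations <- function() {
  data.frame(
    surface_text = c("tissues of ancient mummies", "mummy tissue",
                     "gut of mice"),
    concept_id = c("MBTO:00001875", "MBTO:00001875", "MBTO:09900012"))
}

# Build one fixture standoff document.  Entities are located by substring so
# offsets are never hand-counted.  `spec` rows: list(id, etype, surface,
# occurrence, layer) or, for discontinuous entities, surface = character
# vector of fragment strings with occurrence vector of the same length.
fixture_doc <- function(doc_id, text, entity_spec, relations = empty_relations(),
                        normalizations = empty_normalizations()) {
  entities <- lapply(entity_spec, function(e) {
    frs <- do.call(rbind, Map(function(s, n) span_of(text, s, n),
                              e$surface, e$occurrence %||% rep(1L, length(e$surface))))
    frs <- frs[order(frs$start), , drop = FALSE]
    entity_ref(e$id, e$etype, frs, paste(e$surface, collapse = " "),
               layer = e$layer %||% "a1")
  })
  standoff_document(doc_id, text, entities, normalizations, relations)
}

#' The packaged fixture documents
#'
#' One small standoff document per method scenario: anaphora types 1-3, the
#' paragraph-strategy strain rule, in-sentence pairing, the four coordination
#' phrases, the "animal bodily fluid" double mapping, noun-phrase
#' simplification, the PartOf syntax rules, and prepositional modifier
#' attachment.  Each carries its gold annotations (`.a1` given entities;
#' `.a2` expected output) plus metadata: `task` (`"entities"` or
#' `"relations"`) and, for relation documents, the Localization `strategy`
#' the scenario targets.
#'
#' @return named list; each element has `doc` (a [standoff_document()]),
#'   `task` and `strategy`.
#' @export
build_fixture_documents <- function() {
  docs <- list()
  rel <- function(doc, strategy = "sentence") {
    list(doc = doc, task = "relations", strategy = strategy)
  }
  ent <- function(doc, config = recognition_config()) {
    list(doc = doc, task = "entities", config = config)
  }

  # -- anaphora type 1: listed expression, antecedent in previous sentence
  text <- paste0("Brucella canis.\n\nThis bacterium is highly infectious, ",
                 "and can be spread through the contact with the infected ",
                 "animal products or through the air.\n")
  docs$`brucella-canis` <- rel(fixture_doc(
    "brucella-canis", text,
    list(list(id = "T1", etype = "Bacteria", surface = "Brucella canis"),
         list(id = "T2", etype = "Habitat", surface = "animal products"),
         list(id = "T3", etype = "Habitat", surface = "air")),
    relations = data.frame(id = c("R1", "R2"), rtype = "Localization",
                           arg1 = "T1", arg2 = c("T2", "T3"))))

  # -- anaphora type 2: sentence-initial "it"
  text <- "Borrelia burgdorferi\n\nIt was isolated from Ixodes scapularis in 1982.\n"
  docs$`borrelia-burgdorferi` <- rel(fixture_doc(
    "borrelia-burgdorferi", text,
    list(list(id = "T1", etype = "Bacteria", surface = "Borrelia burgdorferi"),
         list(id = "T2", etype = "Habitat", surface = "Ixodes scapularis")),
    relations = data.frame(id = "R1", rtype = "Localization",
                           arg1 = "T1", arg2 = "T2")))

  # -- anaphora type 3: "This strain" resolves to the document-first bacterium
  text <- "Bifidobacterium longum NCC2705.\n\nThis strain was isolated from infant feces.\n"
  docs$`strain-feces` <- rel(fixture_doc(
    "strain-feces", text,
    list(list(id = "T1", etype = "Bacteria",
              surface = "Bifidobacterium longum NCC2705"),
         list(id = "T2", etype = "Habitat", surface = "infant feces"),
         list(id = "T3", etype = "Habitat", surface = "infant")),
    relations = data.frame(id = c("R1", "R2", "R3"),
                           rtype = c("Localization", "Localization", "PartOf"),
                           arg1 = c("T1", "T1", "T2"),
                           arg2 = c("T2", "T3", "T3"))))

  # -- paragraph strategy with the strain rule: the anchor re-points to the
  #    earlier strain-less mention
  text <- paste0("Bordetella petrii\n\nBordetella petrii DSM12804 is an ",
                 "environmental isolate of the genus.\n\nBordetella petrii ",
                 "strain DSM12804 was initially isolated from river sediment.\n")
  docs$`bordetella-petrii` <- rel(fixture_doc(
    "bordetella-petrii", text,
    list(list(id = "T1", etype = "Bacteria", surface = "Bordetella petrii",
              occurrence = 1L),
         list(id = "T2", etype = "Bacteria", surface = "Bordetella petrii DSM12804"),
         list(id = "T3", etype = "Bacteria",
              surface = "Bordetella petrii strain DSM12804"),
         list(id = "T4", etype = "Habitat", surface = "river sediment")),
    relations = data.frame(id = "R1", rtype = "Localization",
                           arg1 = "T2", arg2 = "T4")),
    strategy = "paragraph")

  # -- in-sentence pairing via a type-1 anaphor + PartOf rule 1
  text <- paste0("Bordetella. This group of organisms is capable of invading ",
                 "the respiratory tract of animals and causing severe diseases.\n")
  docs$`bordetella-group` <- rel(fixture_doc(
    "bordetella-group", text,
    list(list(id = "T1", etype = "Bacteria", surface = "Bordetella"),
         list(id = "T2", etype = "Habitat", surface = "respiratory tract of animals"),
         list(id = "T3", etype = "Habitat", surface = "animals")),
    relations = data.frame(id = c("R1", "R2", "R3"),
                           rtype = c("Localization", "Localization", "PartOf"),
                           arg1 = c("T1", "T1", "T2"),
                           arg2 = c("T2", "T3", "T3"))))

  # -- overlapping habitat + PartOf rule 2 ("human gastrointestinal tract")
  text <- paste0("Bifidobacterium\n\nBifidobacterium longum is a normal ",
                 "inhabitant of the human gastrointestinal tract.\n")
  docs$bifidobacterium <- rel(fixture_doc(
    "bifidobacterium", text,
    list(list(id = "T1", etype = "Bacteria", surface = "Bifidobacterium",
              occurrence = 1L),
         list(id = "T2", etype = "Bacteria", surface = "Bifidobacterium longum"),
         list(id = "T3", etype = "Habitat", surface = "human gastrointestinal tract"),
         list(id = "T4", etype = "Habitat", surface = "human")),
    relations = data.frame(id = c("R1", "R2", "R3"),
                           rtype = c("Localization", "Localization", "PartOf"),
                           arg1 = c("T2", "T2", "T3"),
                           arg2 = c("T3", "T4", "T4"))))

  # -- PartOf syntax rules over four scenarios
  text <- paste0(
    "Pseudomonas fluorescens lives in the rhizosphere of plants.\n",
    "Streptococcus mutans is found in the oral cavity in humans.\n",
    "Borrelia was obtained from a skin lesion from a Lyme disease patient in Europe.\n",
    "Bradyrhizobium was found in the Aeschynomene stem nodule.\n")
  docs$`partof-rules` <- rel(fixture_doc(
    "partof-rules", text,
    list(list(id = "T1", etype = "Bacteria", surface = "Pseudomonas fluorescens"),
         list(id = "T2", etype = "Bacteria", surface = "Streptococcus mutans"),
         list(id = "T3", etype = "Bacteria", surface = "Borrelia"),
         list(id = "T4", etype = "Bacteria", surface = "Bradyrhizobium"),
         list(id = "T5", etype = "Habitat", surface = "rhizosphere of plants"),
         list(id = "T6", etype = "Habitat", surface = "plants"),
         list(id = "T7", etype = "Habitat", surface = "oral cavity in humans"),
         list(id = "T8", etype = "Habitat", surface = "humans"),
         list(id = "T9", etype = "Habitat",
              surface = "skin lesion from a Lyme disease patient in Europe"),
         list(id = "T10", etype = "Habitat",
              surface = "Lyme disease patient in Europe"),
         list(id = "T11", etype = "Habitat", surface = "Aeschynomene stem nodule"),
         list(id = "T12", etype = "Habitat", surface = "Aeschynomene",
              occurrence = 1L)),
    relations = data.frame(
      id = paste0("R", 1:12),
      rtype = c(rep("Localization", 8), rep("PartOf", 4)),
      arg1 = c("T1", "T1", "T2", "T2", "T3", "T3", "T4", "T4",
               "T5", "T7", "T9", "T11"),
      arg2 = c("T5", "T6", "T7", "T8", "T9", "T10", "T11", "T12",
               "T6", "T8", "T10", "T12"))))

  # -- the four coordination phrases (entity detection)
  text <- paste0(
    "Colonization of the pharyngeal and gut mucosa was observed.\n",
    "The bacterium grows in an iron-rich and wet environment.\n",
    "It infects plants and animals.\n",
    "Samples were taken from the mouse and cheese.\n")
  nm <- function(i, ent, ref) data.frame(id = paste0("N", i), entity_id = ent,
                                         referent = ref)
  docs$coordination <- ent(fixture_doc(
    "coordination", text,
    list(list(id = "T1", etype = "Habitat", layer = "a2",
              surface = c("pharyngeal", "mucosa"), occurrence = c(1L, 1L)),
         list(id = "T2", etype = "Habitat", layer = "a2", surface = "gut mucosa"),
         list(id = "T3", etype = "Habitat", layer = "a2",
              surface = "iron-rich and wet environment"),
         list(id = "T4", etype = "Habitat", layer = "a2", surface = "plants"),
         list(id = "T5", etype = "Habitat", layer = "a2", surface = "animals"),
         list(id = "T6", etype = "Habitat", layer = "a2", surface = "mouse"),
         list(id = "T7", etype = "Habitat", layer = "a2", surface = "cheese")),
    normalizations = rbind(
      nm(1, "T1", fixture_id("pharyngeal mucosa")),
      nm(2, "T2", fixture_id("gut mucosa")),
      nm(3, "T3", fixture_id("iron-rich environment")),
      nm(4, "T3", fixture_id("wet environment")),
      nm(5, "T4", fixture_id("plant")),
      nm(6, "T5", fixture_id("animal")),
      nm(7, "T6", fixture_id("mouse")),
      nm(8, "T7", fixture_id("cheese")))))

  # -- partial-match boundary rules ("animal bodily fluid")
  text <- "The animal bodily fluid was collected for analysis.\n"
  docs$`bodily-fluid` <- ent(fixture_doc(
    "bodily-fluid", text,
    list(list(id = "T1", etype = "Habitat", layer = "a2", surface = "animal"),
         list(id = "T2", etype = "Habitat", layer = "a2",
              surface = "animal bodily fluid")),
    normalizations = rbind(nm(1, "T1", fixture_id("animal")),
                           nm(2, "T2", fixture_id("body fluid")))))

  # -- noun-phrase simplification (determiner / possessive pronoun)
  text <- "The mummy tissue was sampled, and its small intestine was examined.\n"
  docs$`mummy-tissue` <- ent(fixture_doc(
    "mummy-tissue", text,
    list(list(id = "T1", etype = "Habitat", layer = "a2", surface = "mummy tissue"),
         list(id = "T2", etype = "Habitat", layer = "a2",
              surface = "small intestine")),
    normalizations = rbind(nm(1, "T1", fixture_id("mummy tissue")),
                           nm(2, "T2", fixture_id("small intestine")))))

  # -- prepositional modifier attachment (opt-in via modifier_preps = "in")
  text <- "An infected infant in Germany was reported.\n"
  docs$`infant-germany` <- ent(fixture_doc(
    "infant-germany", text,
    list(list(id = "T1", etype = "Habitat", layer = "a2",
              surface = "infected infant"),
         list(id = "T2", etype = "Habitat", layer = "a2",
              surface = "infected infant in Germany")),
    normalizations = rbind(nm(1, "T1", fixture_id("infant")),
                           nm(2, "T2", fixture_id("infant")))),
    config = recognition_config(modifier_preps = "in"))

  docs
}

#' Materialize the fixture bundle into a directory
#'
#' Writes the fixture ontology as `ontology.obo` and each fixture document's
#' `.txt`, `.a1` and `.a2` under `<dir>/corpus/`.
#'
#' @param dir output directory.
#' @return invisibly, the directory path.
#' @export
write_fixtures <- function(dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_obo(build_fixture_ontology(), file.path(dir, "ontology.obo"))
  corpus <- file.path(dir, "corpus")
  for (fx in build_fixture_documents()) {
    write_standoff_files(fx$doc, corpus)
  }
  invisible(dir)
}
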