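# End-to-end orchestration over standoff directories: entity detection
# (analyze -> detect -> write .a2), relation extraction (gold .a1 entities ->
# chosen strategy -> .a2), ontology expansion from annotated training data,
# and corpus evaluation.  These functions back the exec/ontohab command-line
# interface; per-document failures are isolated so one bad file does not
# abort a corpus run.

run_per_document <- function(items, f, verbose = TRUE) {
  summaries <- list(); failures <- character()
  for (nm in names(items)) {
    res <- tryCatch(f(items[[nm]]), error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, nm)
      if (verbose) message("[ontohab] ", nm, " FAILED: ", conditionMessage(res))
    } else {
      summaries[[nm]] <- res
      if (verbose) message("[ontohab] ", nm, ": ", res)
    }
  }
  out <- data.frame(doc = names(summaries),
                    summary = unlist(summaries) %||% character())
  attr(out, "failures") <- failures
  out
}

#' Detect and normalize habitat entities over a document directory
#'
#' Reads every `.txt` file, analyzes it, runs [detect_entities()] and writes
#' the resulting entity + normalization `.a2` (and the `.txt` copy) to the
#' output directory.
#'
#' @param input_dir directory with `.txt` files.
#' @param output_dir output directory (created if needed).
#' @param ontology an [obo_ontology()].
#' @param config a [recognition_config()].
#' @param analyzer analyzer for [analyze()].
#' @param verbose log per-document counts via `message()`.
#' @return data.frame of per-document summaries; failed doc ids in
#'   `attr(, "failures")`.
#' @export
run_detect <- function(input_dir, output_dir, ontology,
                       config = recognition_config(),
                       analyzer = lexicon_analyzer(), verbose = TRUE) {
  txts <- sort(list.files(input_dir, pattern = "\\.txt$", full.names = TRUE))
  items <- stats::setNames(txts, sub("\\.txt$", "", basename(txts)))
  run_per_document(items, function(path) {
    text <- readChar(path, file.size(path), useBytes = FALSE)
    Encoding(text) <- "UTF-8"
    doc_id <- sub("\\.txt$", "", basename(path))
    mentions <- detect_entities(analyze(text, analyzer), ontology, config)
    sdoc <- mentions_to_standoff(mentions, doc_id, text)
    write_standoff_files(sdoc, output_dir)
    paste0(length(mentions), " habitat mentions")
  }, verbose = verbose)
}

#' Extract Localization and PartOf relations over a document directory
#'
#' Reads each `.txt` with its gold `.a1` entities, applies the chosen
#' Localization strategy plus (optionally) the PartOf syntax rules, and
#' writes relation `.a2` files referencing the `.a1` entity ids.
#'
#' @inheritParams run_detect
#' @param strategy `"sentence"` (with anaphora resolution) or `"paragraph"`.
#' @param anaphora enable the anaphora resolver (sentence strategy only).
#' @param partof also emit PartOf relations.
#' @param anaphora_cfg an [anaphora_config()].
#' @return as [run_detect()].
#' @export
run_relations <- function(input_dir, output_dir,
                          strategy = c("sentence", "paragraph"),
                          anaphora = TRUE, partof = TRUE,
                          anaphora_cfg = anaphora_config(),
                          analyzer = lexicon_analyzer(), verbose = TRUE) {
  strategy <- match.arg(strategy)
  txts <- sort(list.files(input_dir, pattern = "\\.txt$", full.names = TRUE))
  items <- stats::setNames(txts, sub("\\.txt$", "", basename(txts)))
  run_per_document(items, function(path) {
    a1 <- sub("\\.txt$", ".a1", path)
    if (!file.exists(a1)) stop("missing .a1 for ", basename(path))
    sdoc <- read_standoff_files(path, a1, a2_path = "")  # ignore any a2
    adoc <- analyze(sdoc$text, analyzer)
    rels <- if (strategy == "sentence") {
      extract_sentence_based(adoc, sdoc$entities, anaphora_cfg, anaphora)
    } else {
      extract_paragraph_based(adoc, sdoc$entities)
    }
    if (partof) rels <- rbind(rels, extract_partof(sdoc$entities, adoc))
    rels <- unique(rels)
    rel_df <- if (nrow(rels)) {
      cbind(id = paste0("R", seq_len(nrow(rels))), rels)
    } else empty_relations()
    out <- standoff_document(sdoc$doc_id, sdoc$text, sdoc$entities,
                             relations = rel_df)
    write_standoff_files(out, output_dir)
    paste0(nrow(rels), " relations")
  }, verbose = verbose)
}

#' Expand an ontology from the normalizations of annotated documents
#'
#' Collects (entity surface, concept id) pairs from the normalization lines
#' of every standoff document in a directory and applies
#' [expand_from_annotations()].
#'
#' @param ontology an [obo_ontology()] (or path to an OBO file).
#' @param annotation_dir directory of `.txt`/`.a1`/`.a2` documents.
#' @return the expanded ontology; additions in `attr(, "added")`.
#' @export
run_expand_ontology <- function(ontology, annotation_dir) {
  if (is.character(ontology)) ontology <- parse_obo(ontology)
  docs <- read_standoff_dir(annotation_dir)
  rows <- lapply(docs, function(d) {
    if (!nrow(d$normalizations)) return(NULL)
    ids <- vapply(d$entities, `[[`, "", "id")
    texts <- vapply(d$entities, `[[`, "", "text")
    data.frame(surface_text = texts[match(d$normalizations$entity_id, ids)],
               concept_id = d$normalizations$referent)
  })
  ann <- do.call(rbind, rows)
  if (is.null(ann)) ann <- data.frame(surface_text = character(),
                                      concept_id = character())
  expand_from_annotations(ontology, unique(ann))
}
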