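# Localization and PartOf relation extraction over gold entities.  Two
# strategies for Localization: paragraph-scoped (the first bacterium of a
# paragraph is its topic) and sentence-scoped with a three-type rule-based
# anaphora resolver.  PartOf links overlapping habitat mentions via two
# shallow-syntax rules.

#' Anaphora resolver settings
#'
#' @param type1_expressions lowercase multi-word anaphoric expressions (e.g.
#'   "this organism"); matched as token subsequences.  The packaged default
#'   list of 23 expressions lives in `inst/extdata/anaphora-expressions.txt`
#'   and can be replaced by any one-expression-per-line file.
#' @param type2_pronoun sentence-initial pronoun triggering previous-sentence
#'   resolution; `character()` disables the rule.
#' @param type3_prefix sentence-initial expression triggering
#'   document-first-bacterium resolution; `character()` disables the rule.
#' @return a list of class `anaphora_config`.
#' @export
anaphora_config <- function(type1_expressions = ontohab_anaphora_expressions(),
                            type2_pronoun = "it",
                            type3_prefix = "this strain") {
  structure(list(type1_expressions = tolower(type1_expressions),
                 type2_pronoun = tolower(type2_pronoun),
                 type3_prefix = tolower(type3_prefix)),
            class = "anaphora_config")
}

#' @rdname anaphora_config
#' @param path optional file with one expression per line.
#' @export
ontohab_anaphora_expressions <- function(path = NULL) {
  path <- path %||% system.file("extdata", "anaphora-expressions.txt",
                                package = "ontohab")
  x <- trimws(readLines(path, warn = FALSE))
  tolower(x[nzchar(x)])
}

#' Is a bacteria entity a specific bacterium name?
#'
#' Generic taxon words annotated as Bacteria entities ("bacteria",
#' "bacterium") do not name a specific organism and are excluded from
#' same-sentence pairing.
#'
#' @param entity an [entity_ref()] with `etype == "Bacteria"`.
#' @param generic lowercase generic terms.
#' @return `TRUE` unless the lowercased entity text is a generic term.
#' @export
is_specific_bacteria <- function(entity, generic = c("bacteria", "bacterium")) {
  if (!identical(entity$etype, "Bacteria")) {
    stop("is_specific_bacteria() requires a Bacteria entity, got ", entity$etype)
  }
  !(tolower(entity$text) %in% generic)
}

# Locate each entity's sentence and paragraph by its first fragment start.
entity_positions <- function(doc, entities) {
  sent_start <- vapply(doc$sentences, `[[`, 0L, "start")
  sent_end <- vapply(doc$sentences, `[[`, 0L, "end")
  pos <- vapply(entities, function(e) e$fragments$start[1L], 0L)
  sentence <- vapply(pos, function(p) {
    i <- which(sent_start <= p & p < sent_end)
    if (length(i)) i[1L] else NA_integer_
  }, 0L)
  paragraph <- vapply(pos, function(p) {
    i <- which(doc$paragraphs$start <= p & p < doc$paragraphs$end)
    if (length(i)) i[1L] else NA_integer_
  }, 0L)
  data.frame(start = pos, sentence = sentence, paragraph = paragraph)
}

relation_rows <- function(rtype = character(), arg1 = character(),
                          arg2 = character()) {
  data.frame(rtype = rtype, arg1 = arg1, arg2 = arg2)
}

strip_strain_token <- function(text) {
  toks <- strsplit(text, "[[:space:]]+")[[1L]]
  paste(toks[toks != "strain"], collapse = " ")
}

#' Paragraph-scoped Localization extraction
#'
#' For each paragraph holding at least one bacteria and one habitat or
#' geographical entity, the first bacteria mention of the paragraph anchors a
#' Localization to every habitat/geographical entity of the paragraph.  The
#' anchor is re-pointed to the first document occurrence of the same surface
#' text, after removing a standalone "strain" token if present (so
#' "Bordetella petrii strain DSM12804" anchors to the earlier
#' "Bordetella petrii DSM12804"); if no such earlier mention exists the
#' original anchor is kept.
#'
#' @param doc an `analyzed_document` from [analyze()].
#' @param entities list of [entity_ref()]s with valid positions in `doc`.
#' @return data.frame of relations: `rtype` (`"Localization"`), `arg1`
#'   (bacterium entity id), `arg2` (habitat/geographical entity id).
#' @export
extract_paragraph_based <- function(doc, entities) {
  if (!length(entities)) return(relation_rows())
  pos <- entity_positions(doc, entities)
  etype <- vapply(entities, `[[`, "", "etype")
  ids <- vapply(entities, `[[`, "", "id")
  texts <- vapply(entities, `[[`, "", "text")
  doc_order <- order(pos$start)
  out <- relation_rows()
  for (p in seq_len(nrow(doc$paragraphs))) {
    in_p <- which(pos$paragraph == p)
    bact <- in_p[etype[in_p] == "Bacteria"]
    targ <- in_p[etype[in_p] %in% c("Habitat", "Geographical")]
    if (!length(bact) || !length(targ)) next
    anchor <- bact[order(pos$start[bact])][1L]
    wanted <- strip_strain_token(texts[anchor])
    cand <- doc_order[etype[doc_order] == "Bacteria" &
                        texts[doc_order] == wanted]
    if (length(cand)) anchor <- cand[1L]
    targ <- targ[order(pos$start[targ])]
    out <- rbind(out, relation_rows("Localization", ids[anchor], ids[targ]))
  }
  unique(out)
}

# Is `needle` (vector of tokens) a contiguous subsequence of `haystack`?
token_subseq <- function(haystack, needle) {
  n <- length(needle); h <- length(haystack)
  if (n == 0L || n > h) return(FALSE)
  for (i in seq_len(h - n + 1L)) {
    if (all(haystack[i:(i + n - 1L)] == needle)) return(TRUE)
  }
  FALSE
}

#' Resolve a bacteria anaphor for a sentence
#'
#' Applies, in order: type 1 (the sentence contains a listed anaphoric
#' expression; antecedent is the first bacteria entity of the previous
#' sentence, falling back to the first in the document), type 2 (sentence
#' begins with the pronoun "it"; antecedent is the first bacteria entity of
#' the previous sentence, no fallback), type 3 (sentence begins with "this
#' strain"; antecedent is the first bacteria entity of the document).
#' Intended for sentences without a specific bacteria entity.
#'
#' @param sentence an `analyzed_sentence`.
#' @param doc the `analyzed_document` containing it.
#' @param entities list of [entity_ref()]s.
#' @param config an [anaphora_config()].
#' @return the antecedent [entity_ref()], or `NULL`.
#' @export
resolve_anaphora <- function(sentence, doc, entities,
                             config = anaphora_config()) {
  toks <- tolower(sentence$tokens$surface)
  pos <- entity_positions(doc, entities)
  etype <- vapply(entities, `[[`, "", "etype")
  bact <- which(etype == "Bacteria")
  bact <- bact[order(pos$start[bact])]
  first_in_sentence <- function(s) {
    hit <- bact[pos$sentence[bact] == s]
    if (length(hit)) entities[[hit[1L]]] else NULL
  }
  first_in_doc <- function() if (length(bact)) entities[[bact[1L]]] else NULL
  s <- sentence$sentence_index
  starts_with <- function(expr) {
    e <- strsplit(expr, " ", fixed = TRUE)[[1L]]
    length(toks) >= length(e) && all(toks[seq_along(e)] == e)
  }
  type1 <- any(vapply(config$type1_expressions, function(expr) {
    token_subseq(toks, strsplit(expr, " ", fixed = TRUE)[[1L]])
  }, NA))
  if (isTRUE(type1)) {
    ante <- if (s > 1L) first_in_sentence(s - 1L) else NULL
    return(ante %||% first_in_doc())
  }
  if (length(config$type2_pronoun) && length(toks) &&
      toks[1L] == config$type2_pronoun) {
    if (s == 1L) return(NULL)
    return(first_in_sentence(s - 1L))
  }
  if (length(config$type3_prefix) && starts_with(config$type3_prefix)) {
    return(first_in_doc())
  }
  NULL
}

#' Sentence-scoped Localization extraction with anaphora resolution
#'
#' Every specific bacteria entity of a sentence pairs with every habitat and
#' geographical entity of the same sentence.  A sentence without a specific
#' bacteria entity is handed to [resolve_anaphora()]; a resolved antecedent
#' pairs with the sentence's habitat/geographical entities.  Identical
#' relations are deduplicated document-wide.
#'
#' @inheritParams resolve_anaphora
#' @param anaphora set `FALSE` to disable anaphora resolution entirely.
#' @return data.frame of relations as in [extract_paragraph_based()].
#' @export
extract_sentence_based <- function(doc, entities, config = anaphora_config(),
                                   anaphora = TRUE) {
  if (!length(entities)) return(relation_rows())
  pos <- entity_positions(doc, entities)
  etype <- vapply(entities, `[[`, "", "etype")
  ids <- vapply(entities, `[[`, "", "id")
  out <- relation_rows()
  for (s in seq_along(doc$sentences)) {
    in_s <- which(pos$sentence == s)
    targ <- in_s[etype[in_s] %in% c("Habitat", "Geographical")]
    if (!length(targ)) next
    targ <- targ[order(pos$start[targ])]
    bact <- in_s[etype[in_s] == "Bacteria"]
    specific <- bact[vapply(entities[bact], is_specific_bacteria, NA)]
    if (length(specific)) {
      specific <- specific[order(pos$start[specific])]
      for (b in specific) {
        out <- rbind(out, relation_rows("Localization", ids[b], ids[targ]))
      }
    } else if (anaphora) {
      ante <- resolve_anaphora(doc$sentences[[s]], doc, entities, config)
      if (!is.null(ante)) {
        out <- rbind(out, relation_rows("Localization", ante$id, ids[targ]))
      }
    }
  }
  unique(out)
}

#' PartOf extraction between overlapping habitat mentions
#'
#' Rule 1: habitat A contains habitat B (span containment) and, inside A, B
#' directly follows one of the prepositions "of", "in" or "from" (intervening
#' determiners are skipped, matching the annotated boundaries which may keep
#' an article outside the inner mention).  Rule 2: B is a proper prefix of
#' A's token sequence and rule 1 did not fire.  Both emit PartOf with A as
#' the part and B as the host.
#'
#' @param entities list of [entity_ref()]s.
#' @param doc the `analyzed_document` (used for the token context of rule 1).
#' @return data.frame of relations: `rtype` (`"PartOf"`), `arg1` (part entity
#'   id), `arg2` (host entity id).
#' @export
extract_partof <- function(entities, doc) {
  hab <- entities[vapply(entities, `[[`, "", "etype") == "Habitat"]
  if (length(hab) < 2L) return(relation_rows())
  tokens <- do.call(rbind, lapply(doc$sentences, `[[`, "tokens"))
  out <- relation_rows()
  for (a in hab) {
    cov_a <- fragment_coverage(a$fragments)
    for (b in hab) {
      if (identical(a$id, b$id)) next
      cov_b <- fragment_coverage(b$fragments)
      if (!all(cov_b %in% cov_a) || length(cov_b) == length(cov_a)) next
      b_start <- b$fragments$start[1L]
      # token-aligned check: B must start and end on token boundaries
      if (!(b_start %in% tokens$start) ||
          !(b$fragments$end[nrow(b$fragments)] %in% tokens$end)) next
      rule1 <- FALSE
      before <- which(tokens$end <= b_start & tokens$start %in% cov_a)
      before <- before[order(tokens$start[before])]
      while (length(before)) {
        k <- before[length(before)]
        if (tokens$pos[k] %in% c("DT", "PDT", "PRP$")) {
          before <- before[-length(before)]
          next
        }
        rule1 <- tolower(tokens$surface[k]) %in% c("of", "in", "from")
        break
      }
      rule2 <- !rule1 && b_start == a$fragments$start[1L]
      if (rule1 || rule2) {
        out <- rbind(out, relation_rows("PartOf", a$id, b$id))
      }
    }
  }
  unique(out)
}
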