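# Habitat entity recognition: noun phrases are simplified, optionally
# extended with prepositional modifiers, coordinated phrases are split into
# sub-phrases for discontinuous-entity handling, and candidates are matched
# against the ontology label index with three boundary rules.

#' Recognition settings
#'
#' @param coordination handle coordinated ("X and Y Z") noun phrases as
#'   potentially discontinuous entities.
#' @param modifier_preps character vector of prepositions triggering
#'   NP-prep-NP merging (subset of `c("in", "of", "with")`).  Off by default:
#'   prepositional attachment ambiguity makes merged candidates a net loss on
#'   held-out data, so they are opt-in.
#' @param lemma_matching also match ontology labels against the lemma stream
#'   (so "animals" finds the label "animal"); surface matches win ties.
#' @param match_related index RELATED synonyms for matching in addition to
#'   names and EXACT synonyms.
#' @return a list of class `recognition_config`.
#' @export
recognition_config <- function(coordination = TRUE,
                               modifier_preps = character(),
                               lemma_matching = TRUE,
                               match_related = TRUE) {
  stopifnot(all(modifier_preps %in% c("in", "of", "with")))
  structure(list(coordination = isTRUE(coordination),
                 modifier_preps = modifier_preps,
                 lemma_matching = isTRUE(lemma_matching),
                 match_related = isTRUE(match_related)),
            class = "recognition_config")
}

# A candidate phrase: an ordered (possibly non-contiguous) token subsequence
# of one sentence, carrying its provenance and character fragments (adjacent
# token spans merged, gaps preserved).
candidate_phrase <- function(sentence, token_idx, source = "np",
                             np_range = NULL) {
  token_idx <- sort(unique(as.integer(token_idx)))
  toks <- sentence$tokens[token_idx, , drop = FALSE]
  runs <- split(token_idx, cumsum(c(1L, diff(token_idx) != 1L)))
  frags <- new_fragments(
    vapply(runs, function(r) sentence$tokens$start[r[1L]], 0L),
    vapply(runs, function(r) sentence$tokens$end[r[length(r)]], 0L))
  structure(
    list(token_idx = token_idx,
         surface = toks$surface, lemma = toks$lemma, pos = toks$pos,
         fragments = frags, source = source,
         np_range = np_range %||% c(min(token_idx), max(token_idx))),
    class = "candidate_phrase")
}

#' Simplify a noun phrase into a candidate habitat phrase
#'
#' Drops tokens whose POS marks them as non-informative for habitat naming:
#' determiners (`DT`, `PDT`, `WDT`), possessive pronouns (`PRP$`) and the
#' possessive clitic (`POS`), wherever they occur in the phrase.
#'
#' @param np one row of [extract_noun_phrases()] output (list or data.frame
#'   row with `first`/`last`).
#' @param sentence the `analyzed_sentence` containing it.
#' @return a `candidate_phrase`, or `NULL` if every token was removed.
#' @export
simplify_noun_phrase <- function(np, sentence) {
  idx <- seq.int(np$first, np$last)
  drop <- sentence$tokens$pos[idx] %in% c("DT", "PDT", "WDT", "PRP$", "POS")
  keep <- idx[!drop]
  if (!length(keep)) return(NULL)
  candidate_phrase(sentence, keep, source = "np",
                   np_range = c(np$first, np$last))
}

#' Merge NP-preposition-NP patterns into additional candidates
#'
#' For every pair of noun phrases separated by exactly one preposition token
#' whose surface is in `preps`, an additional merged candidate spanning both
#' (simplified) phrases and the preposition is emitted with source
#' `"modifier-extended"`.  The original candidates are always retained.
#'
#' @param candidates list of `candidate_phrase` objects (one per NP, in
#'   sentence order).
#' @param sentence the `analyzed_sentence`.
#' @param preps prepositions that license merging.
#' @return the input list, plus any merged candidates.
#' @export
attach_modifiers <- function(candidates, sentence, preps) {
  if (!length(preps) || length(candidates) < 2L) return(candidates)
  merged <- list()
  for (i in seq_len(length(candidates) - 1L)) {
    a <- candidates[[i]]; b <- candidates[[i + 1L]]
    gap <- a$np_range[2L] + 1L
    if (gap != b$np_range[1L] - 1L) next      # exactly one token between NPs
    if (sentence$tokens$pos[gap] != "IN") next
    if (!(tolower(sentence$tokens$surface[gap]) %in% preps)) next
    merged[[length(merged) + 1L]] <- candidate_phrase(
      sentence, c(a$token_idx, gap, b$token_idx),
      source = "modifier-extended",
      np_range = c(a$np_range[1L], b$np_range[2L]))
  }
  c(candidates, merged)
}

#' Split a coordinated candidate phrase at "and"
#'
#' A candidate containing exactly one `"and"` token splits into two
#' sub-phrases; with left part L and right part R, the shared head of R is
#' completed onto the left conjunct: sub1 = L + R minus its first token,
#' sub2 = R (so "pharyngeal and gut mucosa" gives "pharyngeal mucosa" /
#' "gut mucosa").  When R is a single token the split is plain
#' ("plants and animals" gives "plants" / "animals").
#'
#' @param candidate a `candidate_phrase`.
#' @param sentence the `analyzed_sentence` it came from.
#' @return list with elements `sub1`, `sub2` (`candidate_phrase`s with source
#'   `"coordination-derived"`), or `NULL` when the candidate has no single
#'   well-placed "and".
#' @export
split_coordination <- function(candidate, sentence) {
  pos_and <- which(tolower(candidate$surface) == "and")
  if (length(pos_and) != 1L) return(NULL)
  n <- length(candidate$token_idx)
  if (pos_and == 1L || pos_and == n) return(NULL)  # degenerate coordination
  left <- candidate$token_idx[seq_len(pos_and - 1L)]
  right <- candidate$token_idx[seq.int(pos_and + 1L, n)]
  if (length(right) >= 2L) {
    sub1 <- c(left, right[-1L])
  } else {
    sub1 <- left
  }
  list(sub1 = candidate_phrase(sentence, sub1, source = "coordination-derived",
                               np_range = candidate$np_range),
       sub2 = candidate_phrase(sentence, right, source = "coordination-derived",
                               np_range = candidate$np_range))
}

#' Match a candidate phrase against the ontology label index
#'
#' Every ontology label (name or synonym) whose normalized token sequence
#' equals a contiguous subsequence of the candidate's surface tokens or lemma
#' tokens yields a match.  For each concept only maximal token ranges are
#' kept, and a surface match is preferred over a lemma match on the same
#' (concept, range).
#'
#' @param candidate a `candidate_phrase`.
#' @param ontology an [obo_ontology()].
#' @param config a [recognition_config()].
#' @return data.frame with columns `concept_id`, `first`, `last` (1-based
#'   token positions within the candidate), `kind` (`exact`,
#'   `prefix_partial`, `internal_partial`), `via` (`surface`/`lemma`) and
#'   `label`; zero rows when nothing matches.
#' @export
match_ontology <- function(candidate, ontology, config = recognition_config()) {
  n <- length(candidate$surface)
  if (n == 0L) stop("empty candidate phrase")
  streams <- list(surface = tolower(candidate$surface))
  if (config$lemma_matching) streams$lemma <- tolower(candidate$lemma)
  rows <- list()
  for (via in names(streams)) {
    toks <- streams[[via]]
    for (i in seq_len(n)) {
      for (j in seq.int(i, n)) {
        key <- normalize_label(paste(toks[i:j], collapse = " "))
        if (!nzchar(key)) next
        ids <- label_lookup(ontology, key, include_related = config$match_related)
        for (id in ids) {
          kind <- if (i == 1L && j == n) "exact"
                  else if (i == 1L) "prefix_partial"
                  else "internal_partial"
          rows[[length(rows) + 1L]] <- data.frame(
            concept_id = id, first = i, last = j, kind = kind,
            via = via, label = key)
        }
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(concept_id = character(), first = integer(),
                      last = integer(), kind = character(),
                      via = character(), label = character()))
  }
  m <- do.call(rbind, rows)
  # surface preferred over lemma for the same (concept, range)
  m <- m[order(m$concept_id, m$first, m$last, m$via != "surface"), , drop = FALSE]
  m <- m[!duplicated(m[c("concept_id", "first", "last")]), , drop = FALSE]
  # keep only maximal ranges per concept
  keep <- rep(TRUE, nrow(m))
  for (k in seq_len(nrow(m))) {
    same <- which(m$concept_id == m$concept_id[k])
    for (o in same) {
      if (o != k && m$first[o] <= m$first[k] && m$last[o] >= m$last[k] &&
          (m$last[o] - m$first[o]) > (m$last[k] - m$first[k])) {
        keep[k] <- FALSE
      }
    }
  }
  m <- m[keep, , drop = FALSE]
  row.names(m) <- NULL
  m
}

# Order matches by preference: exact > prefix_partial > internal_partial,
# then longer token range, then lexicographic concept id.
order_matches <- function(matches) {
  pref <- match(matches$kind, c("exact", "prefix_partial", "internal_partial"))
  matches[order(pref, -(matches$last - matches$first), matches$concept_id), ,
          drop = FALSE]
}

new_habitat_mention <- function(fragments, concept_ids, text) {
  structure(list(fragments = fragments,
                 concept_ids = unique(concept_ids),
                 text = slice_fragments(text, fragments)),
            class = "habitat_mention")
}

#' @export
print.habitat_mention <- function(x, ...) {
  cat("<habitat_mention> \"", x$text, "\" [",
      paste(sprintf("%d-%d", x$fragments$start, x$fragments$end),
            collapse = ";"),
      "] -> ", paste(x$concept_ids, collapse = ", "), "\n", sep = "")
  invisible(x)
}

# Fragments covering candidate tokens first..last (candidate-local positions).
candidate_subfragments <- function(candidate, sentence, first, last) {
  idx <- candidate$token_idx[seq.int(first, last)]
  runs <- split(idx, cumsum(c(1L, diff(idx) != 1L)))
  new_fragments(
    vapply(runs, function(r) sentence$tokens$start[r[1L]], 0L),
    vapply(runs, function(r) sentence$tokens$end[r[length(r)]], 0L))
}

#' Turn ontology matches into habitat mentions via the boundary rules
#'
#' Exact matches and internal partial matches set the entity boundary to the
#' whole candidate phrase; a prefix partial match (starting at the first word
#' but not covering the phrase) sets it to the matching sub-phrase only.
#' Mentions with identical fragments merge, concatenating their concept ids.
#'
#' @param candidate a `candidate_phrase`.
#' @param matches output of [match_ontology()] for that candidate.
#' @param sentence the `analyzed_sentence`.
#' @param text the full document string (for surface rendering).
#' @return list of `habitat_mention` objects.
#' @export
apply_boundary_rules <- function(candidate, matches, sentence, text) {
  if (nrow(matches) == 0L) return(list())
  mentions <- list()
  for (k in seq_len(nrow(matches))) {
    frags <- if (matches$kind[k] == "prefix_partial") {
      candidate_subfragments(candidate, sentence, matches$first[k], matches$last[k])
    } else {
      candidate$fragments
    }
    mentions[[length(mentions) + 1L]] <-
      new_habitat_mention(frags, matches$concept_id[k], text)
  }
  merge_mentions(mentions)
}

merge_mentions <- function(mentions) {
  keys <- vapply(mentions, function(m) fragments_key(m$fragments), "")
  out <- list()
  for (key in unique(keys)) {
    grp <- mentions[keys == key]
    ids <- unique(unlist(lapply(grp, `[[`, "concept_ids")))
    out[[length(out) + 1L]] <-
      structure(list(fragments = grp[[1L]]$fragments, concept_ids = ids,
                     text = grp[[1L]]$text),
                class = "habitat_mention")
  }
  out
}

#' Resolve a coordinated candidate into habitat mentions
#'
#' Both sub-phrases are mapped to their best ontology match (exact over
#' prefix over internal partial, longer ranges first, ties by concept id).
#' If both map and the two concepts share a direct is_a parent, the phrase is
#' one habitat unless both sub-phrases are single noun tokens (then each is
#' its own entity); concepts without a common direct parent always yield two
#' separate entities.  The single merged entity is normalized to both
#' concepts.
#'
#' @param sub1,sub2 sub-phrases from [split_coordination()].
#' @param whole the original coordinated `candidate_phrase`.
#' @param ontology an [obo_ontology()].
#' @param sentence the `analyzed_sentence`.
#' @param text full document string.
#' @param config a [recognition_config()].
#' @return list of `habitat_mention` objects (possibly empty).
#' @export
resolve_coordination <- function(sub1, sub2, whole, ontology, sentence, text,
                                 config = recognition_config()) {
  best <- function(cand) {
    m <- match_ontology(cand, ontology, config)
    if (nrow(m) == 0L) return(NULL)
    order_matches(m)[1L, , drop = FALSE]
  }
  b1 <- best(sub1); b2 <- best(sub2)
  mention_for <- function(cand, b) {
    apply_boundary_rules(cand, b, sentence, text)
  }
  if (is.null(b1) && is.null(b2)) return(list())
  if (is.null(b2)) return(mention_for(sub1, b1))
  if (is.null(b1)) return(mention_for(sub2, b2))
  common <- intersect(direct_parents(ontology, b1$concept_id),
                      direct_parents(ontology, b2$concept_id))
  single_nouns <- length(sub1$token_idx) == 1L && length(sub2$token_idx) == 1L &&
    all(grepl("^NN", c(sub1$pos, sub2$pos)))
  if (length(common) && !single_nouns) {
    return(list(new_habitat_mention(whole$fragments,
                                    c(b1$concept_id, b2$concept_id), text)))
  }
  c(mention_for(sub1, b1), mention_for(sub2, b2))
}

#' Detect and normalize habitat mentions in an analyzed document
#'
#' Orchestrates the recognition pipeline: noun phrases are extracted and
#' simplified, optionally extended with prepositional modifiers, coordinated
#' candidates go through the discontinuous-entity path, all others through
#' matching plus the boundary rules.  Output is deduplicated by (fragments,
#' concepts) and ordered by first fragment start.
#'
#' @param doc an `analyzed_document` from [analyze()].
#' @param ontology an [obo_ontology()].
#' @param config a [recognition_config()].
#' @return list of `habitat_mention` objects.
#' @export
detect_entities <- function(doc, ontology, config = recognition_config()) {
  mentions <- list()
  for (sentence in doc$sentences) {
    nps <- extract_noun_phrases(sentence)
    candidates <- list()
    for (r in seq_len(nrow(nps))) {
      cand <- simplify_noun_phrase(nps[r, ], sentence)
      if (!is.null(cand)) candidates[[length(candidates) + 1L]] <- cand
    }
    candidates <- attach_modifiers(candidates, sentence, config$modifier_preps)
    for (cand in candidates) {
      sp <- if (config$coordination) split_coordination(cand, sentence) else NULL
      found <- if (!is.null(sp)) {
        resolve_coordination(sp$sub1, sp$sub2, cand, ontology, sentence,
                             doc$text, config)
      } else {
        apply_boundary_rules(cand, match_ontology(cand, ontology, config),
                             sentence, doc$text)
      }
      mentions <- c(mentions, found)
    }
  }
  if (!length(mentions)) return(mentions)
  keys <- vapply(mentions, function(m) {
    paste(fragments_key(m$fragments),
          paste(sort(m$concept_ids), collapse = ","), sep = "|")
  }, "")
  mentions <- mentions[!duplicated(keys)]
  ord <- order(vapply(mentions, function(m) m$fragments$start[1L], 0L),
               vapply(mentions, function(m) m$fragments$end[nrow(m$fragments)], 0L))
  mentions[ord]
}

#' Render habitat mentions as a standoff document
#'
#' @param mentions list of `habitat_mention`s from [detect_entities()].
#' @param doc_id document identifier.
#' @param text the document string.
#' @return a [standoff_document()] whose `.a2` layer holds one `T` entity line
#'   per mention and one `N` normalization line per (mention, concept).
#' @export
mentions_to_standoff <- function(mentions, doc_id, text) {
  entities <- list()
  norm_ent <- character(); norm_ref <- character()
  for (i in seq_along(mentions)) {
    m <- mentions[[i]]
    id <- paste0("T", i)
    entities[[i]] <- entity_ref(id, "Habitat", m$fragments, m$text, layer = "a2")
    norm_ent <- c(norm_ent, rep(id, length(m$concept_ids)))
    norm_ref <- c(norm_ref, m$concept_ids)
  }
  normalizations <- data.frame(
    id = sprintf("N%d", seq_along(norm_ent)),
    entity_id = norm_ent, referent = norm_ref)
  standoff_document(doc_id, text, entities, normalizations)
}
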