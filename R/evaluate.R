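# Slot Error Rate scoring.  Each candidate prediction/reference pair scores
# M = J * W, the product of the span Jaccard coefficient J and the
# ancestor-set concept similarity W; the pair's substitution cost is
# S_pair = 1 - M.  SER = (S + D + I) / N over an optimal one-to-one pairing,
# where D counts unmatched references and I unmatched predictions.

#' Span Jaccard similarity between two fragment lists
#'
#' J is the Jaccard coefficient of the sets of character positions covered by
#' the fragments: 1 for identical coverage, 0 for disjoint spans.
#'
#' @param pred_fragments,ref_fragments fragment data.frames (`start`/`end`).
#' @return J in \[0, 1\].
#' @export
jaccard_span <- function(pred_fragments, ref_fragments) {
  a <- fragment_coverage(pred_fragments)
  b <- fragment_coverage(ref_fragments)
  if (!length(a) && !length(b)) stop("both spans empty: Jaccard undefined")
  length(intersect(a, b)) / length(union(a, b))
}

#' Ancestor-set similarity between two ontology concepts
#'
#' W is the Jaccard coefficient of the two concepts' is_a ancestor sets,
#' each including the concept itself, so that W = 1 exactly when the two ids
#' coincide.
#'
#' @param ontology an [obo_ontology()].
#' @param pred_id,ref_id concept ids (must exist).
#' @return W in \[0, 1\].
#' @export
concept_similarity_W <- function(ontology, pred_id, ref_id) {
  a <- ancestors(ontology, pred_id, include_self = TRUE)
  b <- ancestors(ontology, ref_id, include_self = TRUE)
  length(intersect(a, b)) / length(union(a, b))
}

scored_entity <- function(x) {
  # Accepts habitat_mention, entity_ref(+concept_ids), or a bare list with
  # $fragments and $concept_ids.
  list(fragments = x$fragments, concept_ids = x$concept_ids %||% character())
}

pair_score <- function(pred, ref, ontology) {
  J <- jaccard_span(pred$fragments, ref$fragments)
  W <- 0
  if (length(pred$concept_ids) && length(ref$concept_ids)) {
    for (pid in pred$concept_ids) {
      for (rid in ref$concept_ids) {
        W <- max(W, concept_similarity_W(ontology, pid, rid))
      }
    }
  }
  c(J = J, W = W)
}

#' Pair predicted and reference entities one-to-one
#'
#' Candidate pairs are those with positive span overlap (J > 0).  A
#' maximum-weight bipartite matching over M = J * W selects the pairing; a
#' tiny epsilon on each edge prefers, among equal-sum matchings, the one with
#' more matched pairs.  Entities carrying several concept ids use the best W
#' over id pairs.  Unmatched references are deletions, unmatched predictions
#' insertions.
#'
#' @param preds,refs lists of entities (habitat mentions or entity refs with
#'   `fragments` and `concept_ids`).
#' @param ontology an [obo_ontology()].
#' @param method `"optimal"` (default) or `"greedy"` (best-first, for
#'   comparison).
#' @return list with `pairs` (data.frame `pred`, `ref`, `J`, `W`, `M`, `S`),
#'   `unmatched_preds`, `unmatched_refs` (integer indices).
#' @export
pair_entities <- function(preds, refs, ontology,
                          method = c("optimal", "greedy")) {
  method <- match.arg(method)
  preds <- lapply(preds, scored_entity)
  refs <- lapply(refs, scored_entity)
  np <- length(preds); nr <- length(refs)
  edges <- data.frame(pred = integer(), ref = integer(),
                      J = numeric(), W = numeric(), M = numeric())
  for (i in seq_len(np)) {
    for (j in seq_len(nr)) {
      sc <- pair_score(preds[[i]], refs[[j]], ontology)
      if (sc[["J"]] > 0) {
        edges <- rbind(edges, data.frame(pred = i, ref = j, J = sc[["J"]],
                                         W = sc[["W"]], M = sc[["J"]] * sc[["W"]]))
      }
    }
  }
  take <- if (nrow(edges) == 0L) {
    integer()
  } else if (method == "optimal") {
    g <- igraph::make_bipartite_graph(
      c(rep(FALSE, np), rep(TRUE, nr)),
      as.vector(rbind(edges$pred, np + edges$ref)))
    m <- igraph::max_bipartite_match(g, weights = edges$M + 1e-9)
    matched_ref <- m$matching[seq_len(np)] - np
    which(edges$ref == matched_ref[edges$pred])
  } else {
    sel <- integer(); used_p <- logical(np); used_r <- logical(nr)
    for (k in order(-edges$M, edges$pred, edges$ref)) {
      if (!used_p[edges$pred[k]] && !used_r[edges$ref[k]]) {
        sel <- c(sel, k)
        used_p[edges$pred[k]] <- TRUE; used_r[edges$ref[k]] <- TRUE
      }
    }
    sort(sel)
  }
  pairs <- edges[take, , drop = FALSE]
  pairs$S <- 1 - pairs$M
  row.names(pairs) <- NULL
  list(pairs = pairs,
       unmatched_preds = setdiff(seq_len(np), pairs$pred),
       unmatched_refs = setdiff(seq_len(nr), pairs$ref))
}

new_ser_outcome <- function(S, D, I, M_total, N, n_pred) {
  precision <- if (n_pred > 0) M_total / n_pred else 0
  recall <- M_total / N
  fscore <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  structure(list(S = S, D = D, I = I, M_total = M_total, N = N,
                 SER = (S + D + I) / N, recall = recall,
                 precision = precision, fscore = fscore,
                 precision_defined = n_pred > 0),
            class = "ser_outcome")
}

#' @export
print.ser_outcome <- function(x, ...) {
  cat(sprintf(
    "<ser_outcome> SER %.4f (S=%.2f D=%d I=%d M=%.2f N=%.2f) R=%.4f P=%.4f F=%.4f\n",
    x$SER, x$S, x$D, x$I, x$M_total, x$N, x$recall, x$precision, x$fscore))
  invisible(x)
}

#' Score predictions against references with the Slot Error Rate
#'
#' @inheritParams pair_entities
#' @return a `ser_outcome`: S (summed substitution scores), D (deletions), I
#'   (insertions), M_total (summed match scores), N (reference count), SER,
#'   recall M/N, precision M/#predictions and their harmonic mean, plus the
#'   pairing in `attr(, "pairing")`.
#' @export
score_ser <- function(preds, refs, ontology, method = c("optimal", "greedy")) {
  if (!length(refs)) stop("no reference entities: SER undefined")
  pairing <- pair_entities(preds, refs, ontology, method)
  out <- new_ser_outcome(
    S = sum(pairing$pairs$S), D = length(pairing$unmatched_refs),
    I = length(pairing$unmatched_preds), M_total = sum(pairing$pairs$M),
    N = length(refs), n_pred = length(preds))
  attr(out, "pairing") <- pairing
  out
}

#' Slot Error Rate from aggregate totals
#'
#' Recomputes SER and recall from corpus-level totals, using the identity
#' that each matched pair contributes S_pair + M = 1, so the matched-pair
#' count is S + M and the reference count is N = S + M + D.
#'
#' @param S summed substitution score.
#' @param D number of deletions (missed references).
#' @param I number of insertions (spurious predictions).
#' @param M summed match score.
#' @return a `ser_outcome`.
#' @export
ser_from_totals <- function(S, D, I, M) {
  new_ser_outcome(S = S, D = D, I = I, M_total = M, N = S + M + D,
                  n_pred = S + M + I)
}

#' Precision/recall/F over relation sets
#'
#' Exact matching on (relation type, arg1 entity id, arg2 entity id) triples;
#' inputs may carry a `doc` column to scope ids per document.
#'
#' @param pred_relations,ref_relations data.frames with columns `rtype`,
#'   `arg1`, `arg2` and optionally `doc`.
#' @return list with `precision`, `recall`, `fscore`, `tp`, `n_pred`,
#'   `n_ref`, and `precision_defined` (`FALSE` when there are no predictions
#'   and precision defaults to 0).
#' @export
relation_prf <- function(pred_relations, ref_relations) {
  key <- function(d) {
    if (!nrow(d)) return(character())
    doc <- if ("doc" %in% names(d)) d$doc else ""
    unique(paste(doc, d$rtype, d$arg1, d$arg2, sep = "\r"))
  }
  p <- key(pred_relations); r <- key(ref_relations)
  tp <- length(intersect(p, r))
  precision <- if (length(p)) tp / length(p) else 0
  recall <- if (length(r)) tp / length(r) else 0
  fscore <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  list(precision = precision, recall = recall, fscore = fscore,
       tp = tp, n_pred = length(p), n_ref = length(r),
       precision_defined = length(p) > 0)
}

# Extract the scoreable habitat entities (fragments + normalized concepts)
# from a standoff document's annotation layers.
standoff_scored_entities <- function(doc, layer = NULL) {
  ents <- doc$entities
  if (!is.null(layer)) {
    ents <- ents[vapply(ents, `[[`, "", "layer") %in% layer]
  }
  ents <- ents[vapply(ents, `[[`, "", "etype") == "Habitat"]
  lapply(ents, function(e) {
    ids <- doc$normalizations$referent[doc$normalizations$entity_id == e$id]
    list(fragments = e$fragments, concept_ids = ids)
  })
}

#' Corpus-level entity evaluation over standoff directories
#'
#' Scores each prediction document against the reference document with the
#' same id, then aggregates S, D, I and M over the corpus.
#'
#' @param ref_docs,pred_docs named lists of [standoff_document()]s (as from
#'   [read_standoff_dir()]); ids present only in the references count their
#'   habitats as deletions.
#' @param ontology an [obo_ontology()].
#' @return list with `corpus` (a `ser_outcome`) and `per_document`
#'   (data.frame of per-document S/D/I/M/N/SER).
#' @export
evaluate_entities <- function(ref_docs, pred_docs, ontology) {
  per <- data.frame()
  for (id in names(ref_docs)) {
    refs <- standoff_scored_entities(ref_docs[[id]])
    if (!length(refs)) next
    preds <- if (id %in% names(pred_docs)) {
      standoff_scored_entities(pred_docs[[id]])
    } else list()
    pairing <- pair_entities(preds, refs, ontology)
    per <- rbind(per, data.frame(
      doc = id, S = sum(pairing$pairs$S),
      D = length(pairing$unmatched_refs),
      I = length(pairing$unmatched_preds),
      M = sum(pairing$pairs$M), N = length(refs),
      n_pred = length(preds)))
  }
  if (!nrow(per)) stop("no reference habitat entities in corpus")
  per$SER <- (per$S + per$D + per$I) / per$N
  corpus <- new_ser_outcome(S = sum(per$S), D = sum(per$D), I = sum(per$I),
                            M_total = sum(per$M), N = sum(per$N),
                            n_pred = sum(per$n_pred))
  list(corpus = corpus, per_document = per)
}

#' Corpus-level relation evaluation over standoff directories
#'
#' @inheritParams evaluate_entities
#' @return output of [relation_prf()] over document-scoped relation triples.
#' @export
evaluate_relations <- function(ref_docs, pred_docs) {
  collect <- function(docs) {
    rows <- lapply(names(docs), function(id) {
      r <- docs[[id]]$relations
      if (!nrow(r)) return(NULL)
      cbind(doc = id, r[c("rtype", "arg1", "arg2")])
    })
    out <- do.call(rbind, rows)
    if (is.null(out)) {
      out <- data.frame(doc = character(), rtype = character(),
                        arg1 = character(), arg2 = character())
    }
    out
  }
  relation_prf(collect(pred_docs), collect(ref_docs))
}
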