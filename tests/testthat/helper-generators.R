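# Random-instance generators and independent brute-force oracles for the
# property-style tests.

random_word <- function() {
  paste(sample(letters, sample(3:8, 1), replace = TRUE), collapse = "")
}

# Random acyclic ontology: node i may only point at earlier nodes.
random_dag_ontology <- function(n = 20) {
  ids <- sprintf("MBTO:0991%04d", seq_len(n))
  concepts <- lapply(seq_len(n), function(i) {
    k <- if (i == 1L) 0L else sample(0:min(2L, i - 1L), 1L)
    parents <- if (k > 0L) sample(ids[seq_len(i - 1L)], k) else character()
    syn <- if (stats::runif(1) < 0.4) paste("syn", i, random_word()) else character()
    obo_concept(ids[i], paste("concept", i, random_word()),
                exact_synonyms = syn, parents = parents)
  })
  obo_ontology(concepts)
}

# Independent ancestor oracle: naive recursive DFS without memoization.
brute_ancestors <- function(ontology, id) {
  res <- character()
  recurse <- function(x) {
    for (p in ontology$concepts[[x]]$parents) {
      if (!(p %in% res)) {
        res <<- c(res, p)
        recurse(p)
      }
    }
  }
  recurse(id)
  sort(res)
}

# Random scored entity (fragments + concept ids) over a short line, for
# pairing/SER properties.  Concept ids come from the fixture ontology.
random_scored_entity <- function(line_len = 40L, ontology = fixture_ont) {
  n_frag <- if (stats::runif(1) < 0.2) 2L else 1L
  if (n_frag == 1L) {
    s <- sample(0:(line_len - 4L), 1L)
    frags <- ontohab:::new_fragments(s, s + sample(2:6, 1L))
  } else {
    s1 <- sample(0:(line_len %/% 2 - 4L), 1L)
    e1 <- s1 + sample(2:3, 1L)
    s2 <- e1 + sample(2:4, 1L)
    frags <- ontohab:::new_fragments(c(s1, s2), c(e1, s2 + sample(2:4, 1L)))
  }
  list(fragments = frags,
       concept_ids = sample(names(ontology$concepts), sample(1:2, 1L)))
}

# Full candidate edge set (J > 0) for an instance, computed directly from the
# metric primitives.
instance_edges <- function(preds, refs, ontology) {
  rows <- list()
  for (i in seq_along(preds)) {
    for (j in seq_along(refs)) {
      J <- jaccard_span(preds[[i]]$fragments, refs[[j]]$fragments)
      if (J > 0) {
        W <- max(0, vapply(preds[[i]]$concept_ids, function(p) {
          max(vapply(refs[[j]]$concept_ids, function(r) {
            concept_similarity_W(ontology, p, r)
          }, 0))
        }, 0))
        rows[[length(rows) + 1L]] <- data.frame(pred = i, ref = j, M = J * W)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(pred = integer(), ref = integer(), M = numeric()))
  }
  do.call(rbind, rows)
}

# Exhaustive assignment oracle: enumerate every one-to-one matching over the
# candidate edges, maximizing total M and, among ties, the pair count.
oracle_best_matching <- function(edges, np) {
  best <- list(M = -1, k = -1L)
  recurse <- function(i, used, sumM, k) {
    if (i > np) {
      if (sumM > best$M + 1e-12 ||
          (abs(sumM - best$M) <= 1e-12 && k > best$k)) {
        best <<- list(M = sumM, k = k)
      }
      return()
    }
    recurse(i + 1L, used, sumM, k)
    cand <- edges[edges$pred == i & !(edges$ref %in% used), , drop = FALSE]
    for (r in seq_len(nrow(cand))) {
      recurse(i + 1L, c(used, cand$ref[r]), sumM + cand$M[r], k + 1L)
    }
  }
  recurse(1L, integer(), 0, 0L)
  best
}

# Random valid standoff document in canonical (serialized) order.
random_standoff_doc <- function(doc_id = "rand") {
  n <- sample(8:16, 1L)
  words <- replicate(n, random_word())
  text <- paste0(paste(words, collapse = " "), "\n")
  starts <- c(0L, cumsum(nchar(words) + 1L))[seq_len(n)]
  ends <- starts + nchar(words)
  m <- sample(2:5, 1L)
  specs <- lapply(seq_len(m), function(i) {
    if (stats::runif(1) < 0.25 && n >= 5L) {
      a <- sample(seq_len(n - 4L), 1L)
      b <- a + sample(2:3, 1L)
      frags <- ontohab:::new_fragments(c(starts[a], starts[b]), c(ends[a], ends[b]))
    } else {
      a <- sample(seq_len(n - 1L), 1L)
      b <- min(n, a + sample(0:2, 1L))
      frags <- ontohab:::new_fragments(starts[a], ends[b])
    }
    list(frags = frags,
         etype = sample(c("Bacteria", "Habitat", "Geographical"), 1L))
  })
  specs <- specs[order(vapply(specs, function(s) s$frags$start[1L], 0L))]
  entities <- lapply(seq_along(specs), function(i) {
    entity_ref(paste0("T", i), specs[[i]]$etype, specs[[i]]$frags,
               ontohab:::slice_fragments(text, specs[[i]]$frags), layer = "a1")
  })
  etypes <- vapply(entities, `[[`, "", "etype")
  hab <- which(etypes == "Habitat")
  norm <- ontohab:::empty_normalizations()
  for (h in hab) {
    if (stats::runif(1) < 0.7) {
      norm <- rbind(norm, data.frame(
        id = paste0("N", nrow(norm) + 1L), entity_id = paste0("T", h),
        referent = sample(names(fixture_ont$concepts), 1L)))
    }
  }
  rel <- ontohab:::empty_relations()
  bact <- which(etypes == "Bacteria")
  targ <- which(etypes %in% c("Habitat", "Geographical"))
  if (length(bact) && length(targ) && stats::runif(1) < 0.6) {
    rel <- rbind(rel, data.frame(
      id = "R1", rtype = "Localization",
      arg1 = paste0("T", bact[1L]), arg2 = paste0("T", targ[1L])))
  }
  standoff_document(doc_id, text, entities, norm, rel)
}
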