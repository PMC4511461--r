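# OBO ontology store: parse, validate, index, query, and expand an
# is_a-structured habitat ontology (OntoBiotope-style, MBTO:NNNNNNNN ids).

#' Construct a single ontology concept
#'
#' @param id concept identifier (e.g. `"MBTO:00000921"`).
#' @param name preferred label; must be non-empty.
#' @param exact_synonyms,related_synonyms character vectors of synonym labels.
#' @param parents character vector of `is_a` parent concept ids.
#' @param obsolete logical; obsolete concepts are retained in the concept map
#'   but excluded from the label index.
#' @return an object of class `obo_concept`.
#' @export
obo_concept <- function(id, name, exact_synonyms = character(),
                        related_synonyms = character(),
                        parents = character(), obsolete = FALSE) {
  if (!nzchar(id)) stop("concept id must be non-empty")
  if (!nzchar(name)) stop("concept name must be non-empty (id ", id, ")")
  # A synonym that duplicates the name or an earlier synonym of the same
  # concept (case-insensitive) carries no information; drop it.
  seen <- normalize_label(name)
  keep_new <- function(labels) {
    kept <- character()
    for (lab in labels) {
      key <- normalize_label(lab)
      if (!(key %in% seen)) {
        kept <- c(kept, lab)
        seen <<- c(seen, key)
      }
    }
    kept
  }
  exact_synonyms <- keep_new(exact_synonyms)
  related_synonyms <- keep_new(related_synonyms)
  structure(
    list(id = id, name = name,
         exact_synonyms = exact_synonyms,
         related_synonyms = related_synonyms,
         parents = unique(parents), obsolete = isTRUE(obsolete)),
    class = "obo_concept"
  )
}

#' Assemble an ontology from a list of concepts
#'
#' Validates the invariants of the store: unique ids, all `is_a` targets
#' present, and an acyclic is_a graph; then builds the label index mapping
#' each normalized name/synonym to the ids that carry it.
#'
#' @param concepts list of [obo_concept()] objects.
#' @return an object of class `obo_ontology` with elements `concepts` (named
#'   list) and `label_index` (data.frame `label`, `id`, `kind`, `source`).
#' @export
obo_ontology <- function(concepts = list()) {
  ids <- vapply(concepts, `[[`, "", "id")
  if (anyDuplicated(ids)) {
    stop("duplicate concept ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  names(concepts) <- ids
  missing <- setdiff(unique(unlist(lapply(concepts, `[[`, "parents"))), ids)
  if (length(missing)) {
    stop("is_a targets missing from ontology: ",
         paste(sort(missing), collapse = ", "))
  }
  assert_acyclic(concepts)
  structure(
    list(concepts = concepts, label_index = build_label_index(concepts)),
    class = "obo_ontology"
  )
}

assert_acyclic <- function(concepts) {
  # Kahn topological sort over is_a edges (child -> parent).
  indeg <- vapply(concepts, function(co) length(co$parents), 0L)
  children <- list()
  for (co in concepts) {
    for (p in co$parents) children[[p]] <- c(children[[p]], co$id)
  }
  queue <- names(indeg)[indeg == 0L]
  seen <- 0L
  while (length(queue)) {
    v <- queue[[1L]]; queue <- queue[-1L]; seen <- seen + 1L
    # removing v removes the edge child -> v for each child of v
    for (ch in children[[v]]) {
      indeg[[ch]] <- indeg[[ch]] - 1L
      if (indeg[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  if (seen < length(concepts)) stop("is_a graph contains a cycle")
  invisible(TRUE)
}

build_label_index <- function(concepts) {
  rows <- lapply(concepts, function(co) {
    if (co$obsolete) return(NULL)
    data.frame(
      label = normalize_label(c(co$name, co$exact_synonyms, co$related_synonyms)),
      id = co$id,
      kind = c("name",
               rep("exact", length(co$exact_synonyms)),
               rep("related", length(co$related_synonyms))),
      source = c(co$name, co$exact_synonyms, co$related_synonyms)
    )
  })
  rows <- Filter(Negate(is.null), rows)
  if (!length(rows)) {
    return(data.frame(label = character(), id = character(),
                      kind = character(), source = character()))
  }
  out <- do.call(rbind, rows)
  row.names(out) <- NULL
  out
}

#' @export
print.obo_ontology <- function(x, ...) {
  cat("<obo_ontology> ", length(x$concepts), " concepts, ",
      nrow(x$label_index), " indexed labels\n", sep = "")
  invisible(x)
}

concept_or_stop <- function(ontology, id) {
  co <- ontology$concepts[[id]]
  if (is.null(co)) stop("unknown concept id: ", id)
  co
}

#' Look up concept ids by label
#'
#' @param ontology an [obo_ontology()].
#' @param label label string (normalized internally).
#' @param include_related if `FALSE`, only names and EXACT synonyms match.
#' @return character vector of concept ids (possibly empty).
#' @export
label_lookup <- function(ontology, label, include_related = TRUE) {
  idx <- ontology$label_index
  if (!include_related) idx <- idx[idx$kind != "related", , drop = FALSE]
  unique(idx$id[idx$label == normalize_label(label)])
}

#' Direct is_a parents of a concept
#'
#' @inheritParams label_lookup
#' @param id concept id; must exist.
#' @return character vector of parent ids (empty for roots).
#' @export
direct_parents <- function(ontology, id) {
  concept_or_stop(ontology, id)$parents
}

#' Transitive is_a ancestors of a concept
#'
#' @inheritParams direct_parents
#' @param include_self if `TRUE`, the concept itself is part of the set (the
#'   convention used by the concept-similarity term of the SER metric).
#' @return character vector of ancestor ids.
#' @export
ancestors <- function(ontology, id, include_self = FALSE) {
  concept_or_stop(ontology, id)
  out <- character()
  stack <- direct_parents(ontology, id)
  while (length(stack)) {
    v <- stack[[1L]]; stack <- stack[-1L]
    if (v %in% out) next
    out <- c(out, v)
    stack <- c(stack, direct_parents(ontology, v))
  }
  if (include_self) out <- unique(c(id, out))
  sort(out)
}

#' Expand an ontology with surface forms from annotated training data
#'
#' Each training annotation pairs an entity surface string with the concept it
#' was manually labeled with.  The surface string is appended as an EXACT
#' synonym of that concept unless it is already one of the concept's labels
#' (case-insensitive comparison on normalized labels), so repeated application
#' is a no-op.
#'
#' @inheritParams label_lookup
#' @param annotations data.frame with columns `surface_text` and `concept_id`.
#' @return a new `obo_ontology`; the input is not modified.  The additions are
#'   recorded in `attr(, "added")` as a data.frame `concept_id`/`added_synonym`.
#' @export
expand_from_annotations <- function(ontology, annotations) {
  stopifnot(is.data.frame(annotations),
            all(c("surface_text", "concept_id") %in% names(annotations)))
  unknown <- setdiff(unique(annotations$concept_id), names(ontology$concepts))
  if (length(unknown)) {
    stop("annotations reference unknown concept ids: ",
         paste(sort(unknown), collapse = ", "))
  }
  concepts <- ontology$concepts
  added_id <- character(); added_syn <- character()
  for (i in seq_len(nrow(annotations))) {
    id <- annotations$concept_id[i]
    surface <- annotations$surface_text[i]
    co <- concepts[[id]]
    known <- normalize_label(c(co$name, co$exact_synonyms, co$related_synonyms))
    if (!(normalize_label(surface) %in% known)) {
      co$exact_synonyms <- c(co$exact_synonyms, surface)
      concepts[[id]] <- co
      added_id <- c(added_id, id); added_syn <- c(added_syn, surface)
    }
  }
  out <- obo_ontology(concepts)
  attr(out, "added") <- data.frame(concept_id = added_id,
                                   added_synonym = added_syn)
  out
}

#' Parse an OBO 1.2 flat file
#'
#' Reads `[Term]` stanzas with `id:`, `name:`, `synonym: "..." EXACT|RELATED`,
#' `is_a:` and `is_obsolete:` lines.  Non-Term stanzas and unknown tags are
#' ignored.  A synonym line without a scope keyword is treated as RELATED (the
#' OBO 1.2 default).
#'
#' @param x path to an OBO file, or a character vector of OBO lines.
#' @return an [obo_ontology()].
#' @export
parse_obo <- function(x) {
  lines <- if (length(x) == 1L && !grepl("\n", x) && file.exists(x)) {
    readLines(x, warn = FALSE)
  } else {
    unlist(strsplit(x, "\n", fixed = TRUE))
  }
  concepts <- list()
  in_term <- FALSE
  cur <- NULL
  cur_line <- NA_integer_
  flush <- function() {
    if (is.null(cur)) return()
    if (is.null(cur$id)) stop("OBO stanza starting at line ", cur_line,
                              " has no id")
    if (is.null(cur$name)) stop("OBO stanza starting at line ", cur_line,
                                " (", cur$id, ") has no name")
    concepts[[length(concepts) + 1L]] <<- obo_concept(
      cur$id, cur$name, cur$exact %||% character(),
      cur$related %||% character(), cur$parents %||% character(),
      isTRUE(cur$obsolete))
  }
  for (i in seq_along(lines)) {
    line <- sub("\\s+$", "", lines[i])
    if (line == "[Term]") {
      flush(); cur <- list(); cur_line <- i; in_term <- TRUE
    } else if (grepl("^\\[.+\\]$", line)) {
      flush(); cur <- NULL; in_term <- FALSE
    } else if (in_term && nzchar(line)) {
      if (grepl("^id:", line)) {
        cur$id <- sub("^id:\\s*", "", line)
      } else if (grepl("^name:", line)) {
        cur$name <- sub("^name:\\s*", "", line)
      } else if (grepl("^synonym:", line)) {
        m <- regmatches(line, regexec('^synonym:\\s*"(.*)"\\s*([A-Z_]*)', line))[[1L]]
        if (length(m) < 2L) stop("malformed synonym line ", i, ": ", line)
        scope <- if (length(m) >= 3L && m[3L] == "EXACT") "exact" else "related"
        if (scope == "exact") cur$exact <- c(cur$exact, m[2L])
        else cur$related <- c(cur$related, m[2L])
      } else if (grepl("^is_a:", line)) {
        target <- sub("^is_a:\\s*", "", line)
        target <- sub("\\s*!.*$", "", target)
        cur$parents <- c(cur$parents, target)
      } else if (grepl("^is_obsolete:\\s*true", line)) {
        cur$obsolete <- TRUE
      }
    }
  }
  flush()
  obo_ontology(concepts)
}

#' Serialize an ontology to OBO 1.2 text
#'
#' @inheritParams label_lookup
#' @param path optional file path; if given the lines are also written there.
#' @return character vector of OBO lines, invisibly when `path` is given.
#' @export
write_obo <- function(ontology, path = NULL) {
  lines <- c("format-version: 1.2", "")
  for (id in sort(names(ontology$concepts))) {
    co <- ontology$concepts[[id]]
    lines <- c(lines, "[Term]",
               paste0("id: ", co$id),
               paste0("name: ", co$name))
    for (s in co$exact_synonyms) {
      lines <- c(lines, sprintf('synonym: "%s" EXACT []', s))
    }
    for (s in co$related_synonyms) {
      lines <- c(lines, sprintf('synonym: "%s" RELATED []', s))
    }
    for (p in sort(co$parents)) {
      pn <- ontology$concepts[[p]]$name
      lines <- c(lines, paste0("is_a: ", p, " ! ", pn))
    }
    if (co$obsolete) lines <- c(lines, "is_obsolete: true")
    lines <- c(lines, "")
  }
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
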