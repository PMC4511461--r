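# Reader/writer for the BioNLP-ST standoff annotation dialect used by the
# bacteria-biotope corpus: <doc>.txt holds the text, <doc>.a1 the given
# entities, <doc>.a2 predicted/gold entities, OntoBiotope normalizations and
# Localization/PartOf relations.  Offsets are 0-based, end-exclusive, counted
# in characters of the UTF-8 decoded text.

#' Construct an entity reference
#'
#' @param id standoff id (`T` + digits).
#' @param etype entity type: `Bacteria`, `Habitat` or `Geographical`.
#' @param fragments data.frame of `start`/`end` character spans; more than one
#'   row encodes a discontinuous entity.
#' @param text surface string (fragments joined with single spaces).
#' @param layer which annotation file the entity belongs to (`"a1"` or
#'   `"a2"`).
#' @return an object of class `entity_ref`.
#' @export
entity_ref <- function(id, etype, fragments, text, layer = "a1") {
  validate_fragments(fragments, what = paste0("entity ", id, " fragment"))
  structure(list(id = id, etype = etype, fragments = fragments,
                 text = text, layer = layer),
            class = "entity_ref")
}

#' @export
print.entity_ref <- function(x, ...) {
  cat("<entity_ref> ", x$id, " ", x$etype, " \"", x$text, "\"\n", sep = "")
  invisible(x)
}

#' Assemble and validate a standoff document
#'
#' Checks the integrity invariants: every entity's fragments slice the text
#' to its recorded surface (single-space joining across fragments; exact
#' concatenation is also accepted on input), all normalization and relation
#' references resolve, and ids are unique per prefix class.
#'
#' @param doc_id document identifier (file stem).
#' @param text full document string.
#' @param entities list of [entity_ref()] objects.
#' @param normalizations data.frame `id`, `entity_id`, `referent` (ontology
#'   concept id).
#' @param relations data.frame `id`, `rtype` (`Localization`/`PartOf`),
#'   `arg1`, `arg2` (entity ids).  For Localization arg1 is the bacterium and
#'   arg2 the habitat/geographical; for PartOf arg1 is the part and arg2 the
#'   host.
#' @return an object of class `standoff_document`.
#' @export
standoff_document <- function(doc_id, text, entities = list(),
                              normalizations = empty_normalizations(),
                              relations = empty_relations()) {
  ids <- vapply(entities, `[[`, "", "id")
  if (anyDuplicated(ids)) {
    stop("duplicate entity ids in ", doc_id, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  for (e in entities) {
    validate_fragments(e$fragments, nchar(text),
                       what = paste0(doc_id, " entity ", e$id, " fragment"))
    joined <- slice_fragments(text, e$fragments)
    concat <- paste(substring(text, e$fragments$start + 1L, e$fragments$end),
                    collapse = "")
    if (e$text != joined && e$text != concat) {
      stop("entity ", e$id, " in ", doc_id, ": recorded text \"", e$text,
           "\" does not match text at offsets (\"", joined, "\")")
    }
  }
  if (anyDuplicated(normalizations$id)) {
    stop("duplicate normalization ids in ", doc_id)
  }
  if (anyDuplicated(relations$id)) stop("duplicate relation ids in ", doc_id)
  dangling <- setdiff(c(normalizations$entity_id,
                        relations$arg1, relations$arg2), ids)
  if (length(dangling)) {
    stop("dangling entity references in ", doc_id, ": ",
         paste(unique(dangling), collapse = ", "))
  }
  if (any(relations$arg1 == relations$arg2)) {
    stop("relation with identical arguments in ", doc_id)
  }
  if (nrow(relations)) {
    etype_of <- stats::setNames(vapply(entities, `[[`, "", "etype"), ids)
    loc <- relations$rtype == "Localization"
    if (any(etype_of[relations$arg1[loc]] != "Bacteria") ||
        any(!(etype_of[relations$arg2[loc]] %in% c("Habitat", "Geographical")))) {
      stop("Localization relation with wrong argument types in ", doc_id)
    }
    po <- relations$rtype == "PartOf"
    if (any(etype_of[c(relations$arg1[po], relations$arg2[po])] != "Habitat")) {
      stop("PartOf relation with non-Habitat argument in ", doc_id)
    }
  }
  structure(list(doc_id = doc_id, text = text, entities = entities,
                 normalizations = normalizations, relations = relations),
            class = "standoff_document")
}

empty_normalizations <- function() {
  data.frame(id = character(), entity_id = character(), referent = character())
}

empty_relations <- function() {
  data.frame(id = character(), rtype = character(),
             arg1 = character(), arg2 = character())
}

#' @export
print.standoff_document <- function(x, ...) {
  cat("<standoff_document> ", x$doc_id, ": ", length(x$entities),
      " entities, ", nrow(x$normalizations), " normalizations, ",
      nrow(x$relations), " relations\n", sep = "")
  invisible(x)
}

parse_entity_line <- function(line, layer, what) {
  m <- regmatches(line, regexec(
    "^(T[0-9]+)\t([^ \t]+) ([0-9]+ [0-9]+(?:;[0-9]+ [0-9]+)*)\t(.*)$",
    line))[[1L]]
  if (!length(m)) return(NULL)
  pairs <- strsplit(strsplit(m[4L], ";", fixed = TRUE)[[1L]], " ", fixed = TRUE)
  frags <- new_fragments(
    vapply(pairs, function(p) as.integer(p[1L]), 0L),
    vapply(pairs, function(p) as.integer(p[2L]), 0L))
  entity_ref(m[2L], m[3L], frags, m[5L], layer = layer)
}

#' Read a standoff document from its annotation streams
#'
#' @param text full document string (contents of the `.txt` file).
#' @param a1_lines,a2_lines character vectors of annotation lines; `a2_lines`
#'   may be omitted.  Unknown line types are skipped with a warning.
#' @param doc_id document identifier.
#' @return a validated [standoff_document()].
#' @export
read_standoff <- function(text, a1_lines = character(),
                          a2_lines = character(), doc_id = "doc") {
  entities <- list()
  normalizations <- empty_normalizations()
  relations <- empty_relations()
  consume <- function(lines, layer) {
    for (line in lines) {
      if (!nzchar(line)) next
      if (grepl("^T[0-9]+\t", line)) {
        e <- parse_entity_line(line, layer, doc_id)
        if (is.null(e)) stop("malformed entity line in ", doc_id, ": ", line)
        entities[[length(entities) + 1L]] <<- e
      } else if (grepl("^N[0-9]+\t", line)) {
        m <- regmatches(line, regexec(
          "^(N[0-9]+)\t(\\S+) Annotation:(T[0-9]+) Referent:(\\S+)\\s*$",
          line))[[1L]]
        if (!length(m)) stop("malformed normalization line in ", doc_id, ": ", line)
        normalizations <<- rbind(normalizations, data.frame(
          id = m[2L], entity_id = m[4L], referent = m[5L]))
      } else if (grepl("^R[0-9]+\t", line)) {
        m <- regmatches(line, regexec(
          "^(R[0-9]+)\t(\\S+) ([A-Za-z]+):(T[0-9]+) ([A-Za-z]+):(T[0-9]+)\\s*$",
          line))[[1L]]
        if (!length(m)) stop("malformed relation line in ", doc_id, ": ", line)
        rtype <- m[3L]
        args <- stats::setNames(c(m[5L], m[7L]), c(m[4L], m[6L]))
        if (rtype == "Localization") {
          a1v <- args[["Bacterium"]]; a2v <- args[["Localization"]]
        } else if (rtype == "PartOf") {
          a1v <- args[["Part"]]; a2v <- args[["Host"]]
        } else {
          stop("unknown relation type in ", doc_id, ": ", rtype)
        }
        relations <<- rbind(relations, data.frame(
          id = m[2L], rtype = rtype, arg1 = a1v, arg2 = a2v))
      } else {
        warning("skipping unrecognized annotation line in ", doc_id, ": ",
                line, call. = FALSE)
      }
    }
  }
  consume(a1_lines, "a1")
  consume(a2_lines, "a2")
  standoff_document(doc_id, text, entities, normalizations, relations)
}

entity_line <- function(e) {
  offs <- paste(sprintf("%d %d", e$fragments$start, e$fragments$end),
                collapse = ";")
  sprintf("%s\t%s %s\t%s", e$id, e$etype, offs, e$text)
}

#' Serialize a standoff document
#'
#' Entities are ordered by first fragment start then id; normalization and
#' relation lines are renumbered sequentially.  Discontinuous entity text is
#' rendered with single-space joining.
#'
#' @param doc a [standoff_document()].
#' @return list with character vectors `a1` and `a2`.
#' @export
write_standoff <- function(doc) {
  ents <- doc$entities
  ord <- order(vapply(ents, function(e) e$fragments$start[1L], 0L),
               as.integer(sub("^T", "", vapply(ents, `[[`, "", "id"))))
  ents <- ents[ord]
  canon <- lapply(ents, function(e) {
    e$text <- slice_fragments(doc$text, e$fragments)
    e
  })
  layers <- vapply(canon, `[[`, "", "layer")
  a1 <- vapply(canon[layers == "a1"], entity_line, "")
  a2 <- vapply(canon[layers == "a2"], entity_line, "")
  ent_order <- vapply(canon, `[[`, "", "id")
  norms <- doc$normalizations
  if (nrow(norms)) {
    norms <- norms[order(match(norms$entity_id, ent_order)), , drop = FALSE]
    a2 <- c(a2, sprintf("N%d\tOntoBiotope Annotation:%s Referent:%s",
                        seq_len(nrow(norms)), norms$entity_id, norms$referent))
  }
  rels <- doc$relations
  if (nrow(rels)) {
    rels <- rels[order(match(rels$arg1, ent_order),
                       match(rels$arg2, ent_order)), , drop = FALSE]
    body <- ifelse(rels$rtype == "Localization",
                   sprintf("Localization Bacterium:%s Localization:%s",
                           rels$arg1, rels$arg2),
                   sprintf("PartOf Host:%s Part:%s", rels$arg2, rels$arg1))
    a2 <- c(a2, sprintf("R%d\t%s", seq_len(nrow(rels)), body))
  }
  list(a1 = unname(a1), a2 = unname(a2))
}

#' Read a standoff document from files
#'
#' @param txt_path path to the `.txt` file; sibling `.a1`/`.a2` files are
#'   looked up by stem unless given explicitly.
#' @param a1_path,a2_path optional explicit annotation paths; missing files
#'   are treated as empty.
#' @return a [standoff_document()].
#' @export
read_standoff_files <- function(txt_path, a1_path = NULL, a2_path = NULL) {
  stem <- sub("\\.txt$", "", txt_path)
  a1_path <- a1_path %||% paste0(stem, ".a1")
  a2_path <- a2_path %||% paste0(stem, ".a2")
  text <- readChar(txt_path, file.size(txt_path), useBytes = FALSE)
  Encoding(text) <- "UTF-8"
  read_lines_or_empty <- function(p) {
    if (file.exists(p)) readLines(p, warn = FALSE, encoding = "UTF-8")
    else character()
  }
  read_standoff(text, read_lines_or_empty(a1_path), read_lines_or_empty(a2_path),
                doc_id = basename(stem))
}

#' Read every standoff document in a directory
#'
#' Pairs `.txt`, `.a1` and `.a2` files by stem.
#'
#' @param dir directory path.
#' @return named list of [standoff_document()]s, keyed by doc id.
#' @export
read_standoff_dir <- function(dir) {
  txts <- sort(list.files(dir, pattern = "\\.txt$", full.names = TRUE))
  docs <- lapply(txts, read_standoff_files)
  stats::setNames(docs, vapply(docs, `[[`, "", "doc_id"))
}

#' Write a standoff document to files
#'
#' @param doc a [standoff_document()].
#' @param dir output directory (created if needed).
#' @param txt also write the `.txt` file.
#' @return invisibly, the paths written.
#' @export
write_standoff_files <- function(doc, dir, txt = TRUE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  out <- write_standoff(doc)
  paths <- character()
  if (txt) {
    p <- file.path(dir, paste0(doc$doc_id, ".txt"))
    writeChar(doc$text, p, eos = NULL)
    paths <- c(paths, p)
  }
  for (layer in c("a1", "a2")) {
    p <- file.path(dir, paste0(doc$doc_id, ".", layer))
    writeLines(out[[layer]], p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
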