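# Shallow syntactic analysis behind a pluggable analyzer contract.  The
# packaged analyzer is deterministic and lexicon-driven so that the whole
# pipeline runs and is testable without any external POS/chunking models; a
# production adapter can supply its own splitting/tagging functions as long
# as token offsets round-trip against the raw text.

#' Segment a document into paragraphs
#'
#' A paragraph boundary is one or more blank lines (lines containing only
#' whitespace); runs of blank lines collapse.  A leading title line followed
#' by a blank line is therefore its own paragraph, which the paragraph-scoped
#' relation strategy relies on.
#'
#' @param text document string.
#' @return data.frame with 0-based, end-exclusive `start`/`end` spans, one row
#'   per paragraph, covering the non-blank content in order.
#' @export
segment_paragraphs <- function(text) {
  if (!nzchar(text)) return(new_fragments())
  lines <- strsplit(text, "\n", fixed = TRUE)[[1L]]
  # 0-based start offset of each line
  line_start <- c(0L, cumsum(nchar(lines) + 1L))[seq_along(lines)]
  blank <- grepl("^\\s*$", lines)
  starts <- integer(); ends <- integer()
  open <- NA_integer_
  for (i in seq_along(lines)) {
    if (!blank[i]) {
      if (is.na(open)) open <- line_start[i]
      last_end <- line_start[i] + nchar(lines[i])
    }
    if ((blank[i] || i == length(lines)) && !is.na(open)) {
      starts <- c(starts, open); ends <- c(ends, last_end)
      open <- NA_integer_
    }
  }
  new_fragments(starts, ends)
}

# Word-level tokenization of text[start, end): alphanumeric runs with internal
# hyphens/apostrophes stay single tokens ("iron-rich", "2-year-old"); every
# other non-space character is its own token.
tokenize_span <- function(text, start, end) {
  chunk <- substring(text, start + 1L, end)
  m <- gregexpr("[[:alnum:]]+(?:['-][[:alnum:]]+)*|[^[:alnum:][:space:]]",
                chunk, perl = TRUE)[[1L]]
  if (m[1L] == -1L) return(new_fragments())
  s <- start + as.integer(m) - 1L
  new_fragments(s, s + attr(m, "match.length"))
}

# Sentence segmentation within a paragraph: a sentence ends after ".", "!" or
# "?" followed by whitespace or the paragraph end.  A paragraph with no such
# terminator (e.g. a title line) is one sentence.  Abbreviation periods are
# not special-cased; the limitation is documented.
split_sentences_span <- function(text, start, end) {
  chars <- strsplit(substring(text, start + 1L, end), "")[[1L]]
  n <- length(chars)
  bounds <- integer()
  for (i in seq_len(n)) {
    if (chars[i] %in% c(".", "!", "?") &&
        (i == n || grepl("^\\s$", chars[i + 1L]))) {
      bounds <- c(bounds, i)
    }
  }
  cut_end <- unique(c(bounds, n))
  cut_start <- c(0L, cut_end[-length(cut_end)])
  spans <- new_fragments(start + cut_start, start + cut_end)
  # trim surrounding whitespace of each sentence span
  keep_s <- integer(); keep_e <- integer()
  for (i in seq_len(nrow(spans))) {
    piece <- substring(text, spans$start[i] + 1L, spans$end[i])
    lead <- nchar(sub("^(\\s*).*$", "\\1", piece))
    trail <- nchar(sub("^.*?(\\s*)$", "\\1", piece))
    s <- spans$start[i] + lead; e <- spans$end[i] - trail
    if (s < e) { keep_s <- c(keep_s, s); keep_e <- c(keep_e, e) }
  }
  new_fragments(keep_s, keep_e)
}

#' The packaged deterministic lexicon analyzer
#'
#' Tags tokens from a packaged surface/lemma/POS lexicon (Penn Treebank tags),
#' falling back to suffix heuristics for unknown words: all-digit tokens are
#' `CD`, punctuation tags as itself, capitalized unknowns are `NNP` (the
#' position bacteria names occupy), `-ies`/`-s` endings are plural nouns with
#' the singular as lemma, `-ed` endings past participles, anything else `NN`.
#'
#' @param lexicon data.frame with columns `surface`, `lemma`, `pos`; defaults
#'   to the lexicon shipped in `inst/extdata/analyzer-lexicon.tsv`.
#' @return an analyzer object usable with [analyze()].
#' @export
lexicon_analyzer <- function(lexicon = ontohab_lexicon()) {
  stopifnot(all(c("surface", "lemma", "pos") %in% names(lexicon)))
  key <- tolower(lexicon$surface)
  tag <- function(surface) {
    idx <- match(tolower(surface), key)
    lemma <- ifelse(is.na(idx), NA_character_, lexicon$lemma[idx])
    pos <- ifelse(is.na(idx), NA_character_, lexicon$pos[idx])
    for (i in which(is.na(idx))) {
      w <- surface[i]
      if (grepl("^[0-9]+$", w)) {
        pos[i] <- "CD"; lemma[i] <- w
      } else if (grepl("^[^[:alnum:]]$", w)) {
        pos[i] <- w; lemma[i] <- w
      } else if (grepl("^[A-Z]", w)) {
        pos[i] <- "NNP"; lemma[i] <- w
      } else if (grepl("ies$", w)) {
        pos[i] <- "NNS"; lemma[i] <- sub("ies$", "y", w)
      } else if (grepl("[^su]s$", w)) {
        pos[i] <- "NNS"; lemma[i] <- sub("s$", "", w)
      } else if (grepl("ed$", w)) {
        pos[i] <- "VBN"; lemma[i] <- sub("e?d$", "", w)
      } else {
        pos[i] <- "NN"; lemma[i] <- w
      }
    }
    data.frame(lemma = lemma, pos = pos)
  }
  structure(
    list(name = "lexicon",
         split_sentences = split_sentences_span,
         tokenize = tokenize_span,
         tag = tag,
         chunk = chunk_noun_phrases),
    class = "ontohab_analyzer"
  )
}

#' @rdname lexicon_analyzer
#' @export
ontohab_lexicon <- function() {
  path <- system.file("extdata", "analyzer-lexicon.tsv", package = "ontohab")
  utils::read.delim(path, header = TRUE, quote = "", comment.char = "")
}

#' Noun-phrase chunking from POS tags
#'
#' Emits IOB2 chunk labels.  A noun phrase opens at a determiner, possessive,
#' adjective, cardinal, pronoun or noun and continues through adjectives,
#' nouns, cardinals and the possessive clitic.  The conjunction `"and"` is
#' absorbed into a running noun phrase when the following token could continue
#' it, which keeps coordinated phrases such as "pharyngeal and gut mucosa" in
#' one chunk for downstream discontinuous-entity handling.
#'
#' @param pos character vector of Penn Treebank POS tags.
#' @param surface character vector of token surfaces (same length).
#' @return character vector of IOB2 labels (`B-NP`, `I-NP`, `O`).
#' @export
chunk_noun_phrases <- function(pos, surface) {
  n <- length(pos)
  start_pos <- c("DT", "PDT", "PRP$", "PRP", "JJ", "JJR", "JJS",
                 "NN", "NNS", "NNP", "NNPS", "CD")
  cont_pos <- c("JJ", "JJR", "JJS", "NN", "NNS", "NNP", "NNPS", "CD", "POS")
  out <- rep("O", n)
  in_np <- FALSE
  for (i in seq_len(n)) {
    if (in_np && pos[i] %in% cont_pos) {
      out[i] <- "I-NP"
    } else if (in_np && pos[i] == "CC" && tolower(surface[i]) == "and" &&
               i < n && pos[i + 1L] %in% cont_pos) {
      out[i] <- "I-NP"
    } else if (pos[i] %in% start_pos) {
      out[i] <- "B-NP"
      in_np <- TRUE
    } else {
      out[i] <- "O"
      in_np <- FALSE
    }
  }
  out
}

#' Run shallow analysis over a document
#'
#' Segments paragraphs and sentences, tokenizes, tags and chunks, and checks
#' the offset contract: every token surface must equal the slice of the
#' original text at its recorded offsets (0-based, end-exclusive).
#'
#' @param text document string.
#' @param analyzer an analyzer such as [lexicon_analyzer()].
#' @return an `analyzed_document`: list with `text`, `paragraphs` (span
#'   data.frame) and `sentences`, each sentence holding a token data.frame
#'   (`surface`, `lemma`, `pos`, `chunk`, `start`, `end`), its span and its
#'   sentence/paragraph ordinals.
#' @export
analyze <- function(text, analyzer = lexicon_analyzer()) {
  paragraphs <- segment_paragraphs(text)
  sentences <- list()
  sent_i <- 0L
  for (p in seq_len(nrow(paragraphs))) {
    spans <- analyzer$split_sentences(text, paragraphs$start[p], paragraphs$end[p])
    for (s in seq_len(nrow(spans))) {
      sent_i <- sent_i + 1L
      toks <- analyzer$tokenize(text, spans$start[s], spans$end[s])
      surface <- substring(text, toks$start + 1L, toks$end)
      tags <- analyzer$tag(surface)
      chunk <- analyzer$chunk(tags$pos, surface)
      tokens <- data.frame(surface = surface, lemma = tags$lemma,
                           pos = tags$pos, chunk = chunk,
                           start = toks$start, end = toks$end)
      bad <- which(substring(text, tokens$start + 1L, tokens$end) != tokens$surface)
      if (length(bad)) {
        stop("analyzer offset contract violation for token '",
             tokens$surface[bad[1L]], "' at ", tokens$start[bad[1L]])
      }
      sentences[[sent_i]] <- structure(
        list(tokens = tokens, start = spans$start[s], end = spans$end[s],
             sentence_index = sent_i, paragraph_index = p),
        class = "analyzed_sentence")
    }
  }
  structure(list(text = text, sentences = sentences, paragraphs = paragraphs),
            class = "analyzed_document")
}

#' @export
print.analyzed_document <- function(x, ...) {
  cat("<analyzed_document> ", length(x$sentences), " sentences in ",
      nrow(x$paragraphs), " paragraphs, ", nchar(x$text), " chars\n", sep = "")
  invisible(x)
}

#' Extract maximal noun-phrase chunks from a sentence
#'
#' @param sentence an `analyzed_sentence` from [analyze()].
#' @return data.frame with one row per noun phrase: token index range
#'   (`first`, `last`, 1-based within the sentence) and character span
#'   (`start`, `end`).
#' @export
extract_noun_phrases <- function(sentence) {
  chunk <- sentence$tokens$chunk
  first <- integer(); last <- integer()
  i <- 1L
  while (i <= length(chunk)) {
    if (chunk[i] == "B-NP") {
      j <- i
      while (j < length(chunk) && chunk[j + 1L] == "I-NP") j <- j + 1L
      first <- c(first, i); last <- c(last, j)
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  data.frame(first = first, last = last,
             start = sentence$tokens$start[first],
             end = sentence$tokens$end[last])
}
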