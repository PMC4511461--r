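#' Normalize an ontology label or candidate phrase for indexing
#'
#' Lowercases, collapses internal whitespace runs to single spaces, and strips
#' surrounding (but not internal) punctuation, so that `"Body  fluid"` and
#' `"body fluid"` index identically while `"iron-rich environment"` keeps its
#' hyphen.
#'
#' @param x character vector of labels.
#' @return character vector of normalized labels.
#' @export
normalize_label <- function(x) {
  x <- tolower(x)
  x <- gsub("[[:space:]]+", " ", x)
  x <- gsub("^[[:punct:][:space:]]+", "", x)
  x <- gsub("[[:punct:][:space:]]+$", "", x)
  x
}

# Fragments are data.frames with integer columns start/end, 0-based,
# end-exclusive, ordered, non-overlapping.
new_fragments <- function(start = integer(), end = integer()) {
  data.frame(start = as.integer(start), end = as.integer(end))
}

validate_fragments <- function(frags, text_len = NULL, what = "fragment") {
  if (!is.data.frame(frags) || !all(c("start", "end") %in% names(frags))) {
    stop(what, " list must be a data.frame with start/end columns")
  }
  if (nrow(frags) == 0L) stop(what, " list must be non-empty")
  if (any(frags$start >= frags$end)) stop(what, " with start >= end")
  if (any(frags$start < 0L)) stop(what, " with negative offset")
  if (nrow(frags) > 1L) {
    if (is.unsorted(frags$start, strictly = TRUE)) {
      stop(what, "s must be ordered by start")
    }
    if (any(frags$start[-1L] < frags$end[-nrow(frags)])) {
      stop(what, "s must be non-overlapping")
    }
  }
  if (!is.null(text_len) && any(frags$end > text_len)) {
    stop(what, " offset beyond text end (", max(frags$end), " > ", text_len, ")")
  }
  invisible(frags)
}

# Set of 0-based character positions covered by a fragment list.
fragment_coverage <- function(frags) {
  if (nrow(frags) == 0L) return(integer())
  unlist(lapply(seq_len(nrow(frags)), function(i) {
    seq.int(frags$start[i], frags$end[i] - 1L)
  }), use.names = FALSE)
}

# Slice text (0-based offsets) for each fragment and join with single spaces,
# the standoff dialect convention for discontinuous entities.
slice_fragments <- function(text, frags) {
  pieces <- substring(text, frags$start + 1L, frags$end)
  paste(pieces, collapse = " ")
}

# Merge fragments that touch or directly abut (end == next start).
merge_adjacent_fragments <- function(frags) {
  if (nrow(frags) <= 1L) return(frags)
  o <- order(frags$start)
  frags <- frags[o, , drop = FALSE]
  start <- frags$start[1L]
  end <- frags$end[1L]
  out_s <- integer()
  out_e <- integer()
  for (i in seq_len(nrow(frags))[-1L]) {
    if (frags$start[i] <= end) {
      end <- max(end, frags$end[i])
    } else {
      out_s <- c(out_s, start); out_e <- c(out_e, end)
      start <- frags$start[i]; end <- frags$end[i]
    }
  }
  new_fragments(c(out_s, start), c(out_e, end))
}

fragments_key <- function(frags) {
  paste(frags$start, frags$end, sep = "-", collapse = ";")
}

# Locate the nth occurrence of a literal substring; returns 0-based start/end.
# Convenience for building fixtures and tests without hand-counted offsets.
#' @rdname build_fixture_documents
#' @param text document string to search in.
#' @param s literal substring to locate.
#' @param n which occurrence (1 = first).
#' @export
span_of <- function(text, s, n = 1L) {
  hits <- gregexpr(s, text, fixed = TRUE)[[1L]]
  if (hits[1L] == -1L || length(hits) < n) {
    stop("substring not found (occurrence ", n, "): ", s)
  }
  start <- hits[n] - 1L
  new_fragments(start, start + nchar(s))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
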