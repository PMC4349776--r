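# Headword-anchored noun phrase detection.
#
# The chunking rule: locate the headword (a noun); if the token immediately
# to its right is also a noun the phrase is rejected; otherwise extend left
# over adjectives, nouns and numbers as far as possible.  The result is the
# maximal ADJ/NOUN/NUM run ending at the headword.

.NP_TAGS <- c("ADJ", "NOUN", "NUM")

#' Extract the noun phrase anchored at a head token
#'
#' @param sentence A \code{tagged_sentence}.
#' @param head_position 1-based token position of the head; the token must
#'   be tagged \code{NOUN}.
#' @return A \code{noun_phrase} object, or \code{NULL} when the token to
#'   the right of the head is a noun (the phrase is then not a complete
#'   noun phrase and is rejected).
#' @export
extract_noun_phrase <- function(sentence, head_position) {
  stopifnot(inherits(sentence, "tagged_sentence"))
  toks <- sentence$tokens
  n <- nrow(toks)
  if (head_position < 1 || head_position > n) {
    stop("head_position ", head_position, " out of range 1..", n)
  }
  if (toks$tag[head_position] != "NOUN") {
    stop("token at head_position is not a NOUN: ",
         toks$surface[head_position])
  }
  if (head_position < n && toks$tag[head_position + 1L] == "NOUN") {
    return(NULL)
  }
  start <- head_position
  while (start > 1 && toks$tag[start - 1L] %in% .NP_TAGS) {
    start <- start - 1L
  }
  .noun_phrase(sentence, start, head_position)
}

# Internal constructor; start..head inclusive, span stored half-open.
.noun_phrase <- function(sentence, start, head) {
  structure(
    list(tokens = sentence$tokens[start:head, , drop = FALSE],
         head_index = as.integer(head),
         sentence_index = sentence$index,
         start = as.integer(start),
         end = as.integer(head + 1L)),
    class = "noun_phrase")
}

#' @export
print.noun_phrase <- function(x, ...) {
  cat("<noun_phrase> \"", paste(x$tokens$surface, collapse = " "),
      "\" [sentence ", x$sentence_index, ", tokens ", x$start, "..",
      x$end - 1L, "]\n", sep = "")
  invisible(x)
}

# Left-maximal ADJ/NOUN/NUM chunk ending at an anchor token, used for the
# X slot of the appositive and hyponymy patterns.  Unlike
# extract_noun_phrase it does not apply the no-noun-to-the-right rule (the
# anchor is followed by a comma or a link verb by construction) but it does
# require the anchor itself to be chunkable and the chunk head to be a noun.
.chunk_left <- function(sentence, anchor) {
  toks <- sentence$tokens
  if (anchor < 1 || anchor > nrow(toks)) return(NULL)
  if (!(toks$tag[anchor] %in% .NP_TAGS)) return(NULL)
  if (toks$tag[anchor] != "NOUN") return(NULL)
  start <- anchor
  while (start > 1 && toks$tag[start - 1L] %in% .NP_TAGS) {
    start <- start - 1L
  }
  .noun_phrase(sentence, start, anchor)
}

#' Find all noun phrases anchored at a headword in a record
#'
#' Scans every tagged sentence of the record for tokens whose lemma (or
#' surface form, under \code{match = "surface"}) equals the headword, and
#' returns the noun phrase anchored at each such token, in span order.
#' Headword occurrences with a noun immediately to the right yield nothing.
#'
#' @param record A tagged \code{\link{abstract_record}}.
#' @param headword Headword string, e.g. \code{"protein"}.
#' @param match \code{"lemma"} (default; "cells" matches headword "cell")
#'   or \code{"surface"} (exact case-folded form).
#' @return List of \code{noun_phrase} objects ordered by
#'   (sentence, start position).
#' @export
find_headword_noun_phrases <- function(record, headword,
                                       match = c("lemma", "surface")) {
  match <- match.arg(match)
  stopifnot(inherits(record, "abstract_record"))
  if (is.null(record$sentences)) stop("record is not tagged; run tag_record()")
  key <- if (match == "lemma") lemmatize(headword) else tolower(headword)
  out <- list()
  for (s in record$sentences) {
    toks <- s$tokens
    hits <- which(toks$tag == "NOUN" &
                    (if (match == "lemma") toks$lemma else
                       tolower(toks$surface)) == key)
    for (h in hits) {
      np <- extract_noun_phrase(s, h)
      if (!is.null(np)) out[[length(out) + 1L]] <- np
    }
  }
  out
}
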