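# Bigram compatibility: a vocabulary term is consistent with a corpus when
# every contiguous word bigram of the term occurs somewhere in the corpus.
# This is the screen used to keep only corpus-compatible vocabulary entries
# (and, at scale, to shrink training sets).  Bigrams are harvested within
# sentences only and, by default, from lemmatized case-folded tokens.

#' Build a bigram index from a tagged corpus
#'
#' Collects every within-sentence contiguous word bigram (punctuation
#' tokens excluded) of the corpus.
#'
#' @param corpus List of tagged \code{\link{abstract_record}} objects.
#' @param lemmatized Use lemmas (default) or case-folded surface forms.
#' @return A \code{bigram_index}: sorted character vector of
#'   space-separated word pairs.
#' @export
build_bigram_index <- function(corpus, lemmatized = TRUE) {
  grams <- lapply(corpus, function(rec) {
    if (is.null(rec$sentences)) {
      stop("record ", rec$record_id, " is not tagged; run tag_corpus()")
    }
    unlist(lapply(rec$sentences, function(s) {
      toks <- s$tokens[s$tokens$tag != "PUNCT", , drop = FALSE]
      w <- if (lemmatized) toks$lemma else tolower(toks$surface)
      n <- length(w)
      if (n < 2) return(character(0))
      paste(w[-n], w[-1])
    }), use.names = FALSE)
  })
  out <- sort(unique(unlist(grams, use.names = FALSE)))
  if (is.null(out)) out <- character(0)
  structure(out, lemmatized = lemmatized, class = "bigram_index")
}

#' @export
print.bigram_index <- function(x, ...) {
  cat("<bigram_index> ", length(x), " distinct bigrams\n", sep = "")
  invisible(x)
}

#' Test a term for bigram compatibility with a corpus
#'
#' \code{TRUE} iff every contiguous word bigram of the term is present in
#' the index.  Single-word terms have no bigrams and are vacuously
#' compatible.
#'
#' @param term Term string (will be tokenized and normalized to match the
#'   index).
#' @param index A \code{\link{build_bigram_index}} result.
#' @return Logical scalar.
#' @export
bigram_compatible <- function(term, index) {
  stopifnot(inherits(index, "bigram_index"))
  if (!nzchar(trimws(term))) stop("empty term")
  toks <- tokenize(term)
  toks <- toks[grepl("[[:alnum:]]", toks)]
  if (length(toks) == 0) stop("term contains no words: ", term)
  lemmatized <- attr(index, "lemmatized")
  w <- if (isTRUE(lemmatized)) lemmatize(toks) else tolower(toks)
  if (length(w) < 2) return(TRUE)
  all(paste(w[-length(w)], w[-1]) %in% unclass(index))
}

#' Write a bigram index to a sorted text file
#' @param index A \code{bigram_index}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_bigram_index <- function(index, path) {
  writeLines(unclass(index), path, useBytes = TRUE)
  invisible(path)
}
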